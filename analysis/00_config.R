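# Shared settings for the analysis drivers. Intermediates are cached under
# scratch/ (large/binary, not part of the deliverable); tables land in
# results/. Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate.R && Rscript analysis/02_extract.R && ...

library(insilico16S)

SEED <- 2024L
RESULTS <- "results"
CACHE <- "scratch/analysis_cache"
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
dir.create(CACHE, showWarnings = FALSE, recursive = TRUE)

# community scale: a one-third-scale analog of a five-site skin cohort
N_SPECIES <- 120L
N_GENERA <- 40L
SAMPLES_PER_SITE <- c(InaS = 10L, CiraS = 10L, PaS = 10L, NaS = 7L,
                      OrE = 10L)
READS_PER_SAMPLE <- 200L
SUBSTITUTION_RATE <- 0.001
MIN_COUNT <- 2L          # variant filter: singletons are mostly lone errors

REGIONS <- default_regions()
SUBREGIONS <- setdiff(names(REGIONS), "V1-V9")

cache_path <- function(name) file.path(CACHE, paste0(name, ".rds"))
load_cache <- function(name) {
  p <- cache_path(name)
  if (!file.exists(p)) {
    stop("missing intermediate '", name,
         "': run the earlier analysis scripts first")
  }
  readRDS(p)
}
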