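#' Construct a degenerate primer
#'
#' @param name Primer name (e.g. `"27F"`).
#' @param sequence IUPAC string, written 5'->3'. Reverse primers are written
#'   5'->3' on the reverse strand, as primers are ordered from vendors.
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `primer`.
#' @export
primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  ch <- strsplit(sequence, "")[[1]]
  bad <- which(!ch %in% names(IUPAC_CODES))
  if (nchar(sequence) == 0L) stop("empty primer sequence")
  if (length(bad)) {
    stop("invalid IUPAC code '", ch[bad[1]], "' at position ", bad[1],
         " of primer ", name)
  }
  structure(list(name = name, sequence = sequence, orientation = orientation),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer %s (%s): %s>\n", x$name, x$orientation, x$sequence))
  invisible(x)
}

#' Canonical 16S primers
#'
#' The degenerate primers routinely used to delimit 16S hypervariable
#' regions: 27F/1492R flank the near-complete gene, the remainder sit in the
#' internal conserved stretches.
#'
#' @return Named list of [primer] objects.
#' @export
default_primers <- function() {
  list(
    `27F`   = primer("27F",   "AGRGTTTGATYNTGGCTCAG",   "forward"),
    `338R`  = primer("338R",  "TGCTGCCTCCCGTAGGAGT",    "reverse"),
    `341F`  = primer("341F",  "CCTACGGGNGGCWGCAG",      "forward"),
    `515F`  = primer("515F",  "GTGYCAGCMGCCGCGGTAA",    "forward"),
    `534R`  = primer("534R",  "ATTACCGCGGCTGCTGG",      "reverse"),
    `799F`  = primer("799F",  "AACMGGATTAGATACCCKG",    "forward"),
    `805R`  = primer("805R",  "GACTACHVGGGTATCTAATCC",  "reverse"),
    `806R`  = primer("806R",  "GGACTACNVGGGTWTCTAAT",   "reverse"),
    `1492R` = primer("1492R", "TASGGHTACCTTGTTASGACTT", "reverse")
  )
}

#' Define a sub-region by its primer pair
#'
#' @param name Region name (e.g. `"V3-V4"`).
#' @param forward,reverse [primer] objects delimiting the region.
#' @param max_mismatches Per-primer mismatch budget applied independently to
#'   the forward and the reverse primer (default 4).
#' @return An object of class `region_def`.
#' @export
region_def <- function(name, forward, reverse, max_mismatches = 4L) {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"),
            forward$orientation == "forward",
            reverse$orientation == "reverse",
            max_mismatches >= 0)
  structure(list(name = name, forward = forward, reverse = reverse,
                 max_mismatches = as.integer(max_mismatches)),
            class = "region_def")
}

#' Default region set
#'
#' The six region definitions compared throughout the pipeline: V1-V2
#' (27F/338R), V1-V3 (27F/534R), V3-V4 (341F/805R), V4 (515F/806R), V5-V9
#' (799F/1492R) and the near-full-length V1-V9 (27F/1492R).
#'
#' @param max_mismatches Per-primer mismatch budget (default 4).
#' @return Named list of [region_def] objects.
#' @export
default_regions <- function(max_mismatches = 4L) {
  p <- default_primers()
  list(
    `V1-V2` = region_def("V1-V2", p$`27F`,  p$`338R`,  max_mismatches),
    `V1-V3` = region_def("V1-V3", p$`27F`,  p$`534R`,  max_mismatches),
    `V3-V4` = region_def("V3-V4", p$`341F`, p$`805R`,  max_mismatches),
    `V4`    = region_def("V4",    p$`515F`, p$`806R`,  max_mismatches),
    `V5-V9` = region_def("V5-V9", p$`799F`, p$`1492R`, max_mismatches),
    `V1-V9` = region_def("V1-V9", p$`27F`,  p$`1492R`, max_mismatches)
  )
}
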