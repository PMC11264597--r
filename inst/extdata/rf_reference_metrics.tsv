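region	site	precision	recall	f1	overall_accuracy
V1-V9	InaS	57.14	88.89	69.56	73.81
V1-V9	CiraS	66.67	44.44	53.33	73.81
V1-V9	PaS	71.43	55.56	62.50	73.81
V1-V9	NaS	83.33	83.33	83.33	73.81
V1-V9	OrE	100.00	100.00	100.00	73.81
V1-V2	InaS	57.14	88.89	69.56	78.57
V1-V2	CiraS	66.67	66.67	66.67	78.57
V1-V2	PaS	100.00	66.67	80.00	78.57
V1-V2	NaS	100.00	66.67	80.00	78.57
V1-V2	OrE	100.00	100.00	100.00	78.57
V1-V3	InaS	57.14	88.89	69.56	80.95
V1-V3	CiraS	71.43	55.56	62.50	80.95
V1-V3	PaS	100.00	77.78	87.50	80.95
V1-V3	NaS	100.00	83.33	90.91	80.95
V1-V3	OrE	100.00	100.00	100.00	80.95
V3-V4	InaS	66.67	88.89	76.19	80.95
V3-V4	CiraS	62.50	55.56	58.83	80.95
V3-V4	PaS	100.00	66.67	80.00	80.95
V3-V4	NaS	85.71	100.00	92.31	80.95
V3-V4	OrE	100.00	100.00	100.00	80.95
V4	InaS	66.67	88.89	76.19	83.33
V4	CiraS	75.00	66.67	70.59	83.33
V4	PaS	100.00	66.67	80.00	83.33
V4	NaS	85.71	100.00	92.31	83.33
V4	OrE	100.00	100.00	100.00	83.33
V5-V9	InaS	61.54	88.89	72.73	80.95
V5-V9	CiraS	66.67	66.67	66.67	80.95
V5-V9	PaS	100.00	66.67	80.00	80.95
V5-V9	NaS	100.00	83.33	90.91	80.95
V5-V9	OrE	100.00	100.00	100.00	80.95
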