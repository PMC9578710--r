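# Synthetic placeholder AKT signature gene list (one gene per line).
# These are NOT the published signature genes: supply your own list
# (same format) for real analyses.
AKT_SYNTH_01
AKT_SYNTH_02
AKT_SYNTH_03
AKT_SYNTH_04
AKT_SYNTH_05
AKT_SYNTH_06
AKT_SYNTH_07
AKT_SYNTH_08
AKT_SYNTH_09
AKT_SYNTH_10
AKT_SYNTH_11
AKT_SYNTH_12
AKT_SYNTH_13
AKT_SYNTH_14
AKT_SYNTH_15
AKT_SYNTH_16
AKT_SYNTH_17
AKT_SYNTH_18
AKT_SYNTH_19
AKT_SYNTH_20
AKT_SYNTH_21
AKT_SYNTH_22
AKT_SYNTH_23
AKT_SYNTH_24
AKT_SYNTH_25
AKT_SYNTH_26
AKT_SYNTH_27
AKT_SYNTH_28
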