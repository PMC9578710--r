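# Synthetic placeholder YAP signature gene list (one gene per line).
# These are NOT the published signature genes: supply your own list
# (same format) for real analyses.
YAP_SYNTH_01
YAP_SYNTH_02
YAP_SYNTH_03
YAP_SYNTH_04
YAP_SYNTH_05
YAP_SYNTH_06
YAP_SYNTH_07
YAP_SYNTH_08
YAP_SYNTH_09
YAP_SYNTH_10
YAP_SYNTH_11
YAP_SYNTH_12
YAP_SYNTH_13
YAP_SYNTH_14
YAP_SYNTH_15
YAP_SYNTH_16
YAP_SYNTH_17
YAP_SYNTH_18
YAP_SYNTH_19
YAP_SYNTH_20
YAP_SYNTH_21
YAP_SYNTH_22
YAP_SYNTH_23
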