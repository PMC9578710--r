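# Synthetic placeholder ROS signature gene list (one gene per line).
# These are NOT the published signature genes: supply your own list
# (same format) for real analyses.
ROS_SYNTH_01
ROS_SYNTH_02
ROS_SYNTH_03
ROS_SYNTH_04
ROS_SYNTH_05
ROS_SYNTH_06
ROS_SYNTH_07
ROS_SYNTH_08
ROS_SYNTH_09
ROS_SYNTH_10
ROS_SYNTH_11
ROS_SYNTH_12
ROS_SYNTH_13
ROS_SYNTH_14
ROS_SYNTH_15
ROS_SYNTH_16
ROS_SYNTH_17
ROS_SYNTH_18
ROS_SYNTH_19
ROS_SYNTH_20
ROS_SYNTH_21
ROS_SYNTH_22
ROS_SYNTH_23
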