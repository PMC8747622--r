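# Published IRIV band list (26 bands of 176).
477.1
490.3
510.1
526.7
597.3
600.7
610.9
614.3
617.7
624.6
628.0
638.3
648.6
676.2
725.1
728.7
839.3
853.8
861.1
868.4
875.7
879.3
894.0
916.0
945.6
979.2
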