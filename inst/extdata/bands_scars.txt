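# Published sCARS band list (46 bands of 176).
386.6
392.9
402.5
415.4
431.5
526.7
530.0
590.5
593.9
597.3
600.7
610.9
614.3
617.7
624.6
641.7
645.1
676.2
679.7
683.2
693.6
711.1
718.1
732.2
832.1
850.2
853.8
868.4
872.0
875.7
879.3
890.3
894.0
916.0
919.7
923.4
927.1
930.8
938.2
945.6
953.0
960.5
971.7
979.2
982.9
986.7
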