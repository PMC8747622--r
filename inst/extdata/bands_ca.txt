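# Published correlation-screening band list (76 bands of 176).
# The 771.1-990.4 nm stretch was printed as a range covering 61
# bands; it is reconstructed here (synthetic reconstruction) from
# the instrument wavelengths known to lie inside it, with evenly
# spaced fill at the ~3.66 nm grid spacing.
533.3
536.7
540.0
543.4
546.7
550.1
553.4
556.8
560.1
697.1
700.6
704.1
707.6
711.1
767.6
771.1
774.7
778.3
781.9
785.5
789.0
792.6
796.2
799.8
803.4
807.0
810.6
814.2
817.7
821.3
824.9
828.5
832.1
835.7
839.3
842.9
846.6
850.2
853.8
857.5
861.1
864.8
868.4
872.0
875.7
879.3
883.0
886.6
890.3
894.0
897.7
901.3
905.0
908.7
912.3
916.0
919.7
923.4
927.1
930.8
934.5
938.2
941.9
945.6
949.3
953.0
956.8
960.5
964.2
968.0
971.7
975.5
979.2
982.9
986.7
990.4
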