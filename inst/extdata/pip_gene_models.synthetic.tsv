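gene_id	seq_id	strand	start	end
CcPIP4;1	scaffold_CcPIP4;1	+	1	311
CcPIP4;1	scaffold_CcPIP4;1	+	506	654
CcPIP4;1	scaffold_CcPIP4;1	+	820	1157
CcPIP4;1	scaffold_CcPIP4;1	+	1322	1381
CcPIP4;2	scaffold_CcPIP4;2	-	1	60
CcPIP4;2	scaffold_CcPIP4;2	-	135	472
CcPIP4;2	scaffold_CcPIP4;2	-	543	691
CcPIP4;2	scaffold_CcPIP4;2	-	850	1160
PpPIP1;1	scaffold_PpPIP1;1	+	1	448
PpPIP1;1	scaffold_PpPIP1;1	+	535	716
PpPIP1;1	scaffold_PpPIP1;1	+	911	1066
PpPIP1;1	scaffold_PpPIP1;1	+	1127	1186
PpPIP2;1	scaffold_PpPIP2;1	+	1	448
PpPIP2;1	scaffold_PpPIP2;1	+	529	710
PpPIP2;1	scaffold_PpPIP2;1	+	799	954
PpPIP2;1	scaffold_PpPIP2;1	+	1145	1204
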