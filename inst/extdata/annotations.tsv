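# generated-by: mirep 0.1.0
# seed: 11
# alpha: 0.05
# min_expr: 0.004
# command: simulate --seed 11 --n-targets 6 --out-dir inst/extdata
gene_id	programs	mirtarbase	n_mres	score_TargetScan	score_miRanda	score_PicTar
g0001	miRanda	FALSE	1	0.0508445624332613	12.9486437631079	4.78612850488443
g0002	miRanda;PicTar;TargetScan	FALSE	1	-0.726665649503646	-41.3482262498656	9.79086760037107
g0003	miRanda;PicTar	FALSE	1	0.418833513718427	-25.4588343056121	4.34633886770832
g0004	miRanda;TargetScan	TRUE	1	-0.606541745233495	-15.1517837282728	3.41418883283764
g0005	PicTar;TargetScan	FALSE	1	-0.26956881235804	-69.5774307834425	1.65781569206443
g0006	miRanda;PicTar	FALSE	1	0.0587087227696554	-55.8233877327307	6.14793279077626
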