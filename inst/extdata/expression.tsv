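# generated-by: mirep 0.1.0
# seed: 11
# alpha: 0.05
# min_expr: 0.004
# command: simulate --seed 11 --n-targets 6 --out-dir inst/extdata
gene_id	abundance
g0002	12.6246167016512
g0003	2.04159796269881
g0004	3.02308048401568
g0005	38.1727104473841
g0006	14.8797404828571
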