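# generated-by: mirep 0.1.0
# seed: 11
# alpha: 0.05
# min_expr: 0.004
# command: simulate --seed 11 --n-targets 6 --out-dir inst/extdata
construct_id	condition	replicate	firefly	renilla
g0001	control	1	111352733.121901	81994.33773662
g0001	control	2	110976718.113994	81717.4599206204
g0001	control	3	95853052.2089653	70581.1821188426
g0001	mir	1	125167113.93333	79117.924422382
g0001	mir	2	126302928.350902	97966.4738588451
g0001	mir	3	99286592.2449819	93956.2366396472
g0002	control	1	61228630.6968999	108605.476399973
g0002	control	2	57739621.5225431	102416.778412905
g0002	control	3	64565727.4819599	114524.716827354
g0002	mir	1	32031969.4911111	103814.620687644
g0002	mir	2	31943556.6947768	123319.564249474
g0002	mir	3	18870773.6225767	70266.5877026087
g0003	control	1	50416302.3035926	86875.8863410384
g0003	control	2	43234637.4948553	74500.6531891452
g0003	control	3	51255477.2223281	88321.9278301844
g0003	mir	1	27241696.9278965	84891.8072488096
g0003	mir	2	48243773.9228465	133512.708017345
g0003	mir	3	44907571.5004778	126975.580311615
g0004	control	1	90418345.8400203	86619.6248752252
g0004	control	2	101081403.545543	96834.6984855013
g0004	control	3	85419930.8413016	81831.2069038794
g0004	mir	1	80307285.9495032	148023.013773314
g0004	mir	2	50570841.4929231	107007.224769484
g0004	mir	3	51152950.5657056	114643.166595378
g0005	control	1	90277889.0307508	100879.10302786
g0005	control	2	98933369.2127132	110550.98488516
g0005	control	3	79840589.7898763	89216.1654386335
g0005	mir	1	39561464.5453916	75390.4232767628
g0005	mir	2	51967804.3993814	96520.7591735544
g0005	mir	3	56021955.8957519	108467.792875452
g0006	control	1	61838023.4068842	88398.1009890216
g0006	control	2	60823293.8076816	86947.5344177609
g0006	control	3	54944850.482271	78544.2382237878
g0006	mir	1	41929012.4333339	98351.3145362569
g0006	mir	2	29304343.4986126	69938.8621160872
g0006	mir	3	43826391.6594884	103196.637819695
posctrl_b01	control	1	160669419.552488	103470.161185624
posctrl_b01	control	2	259401276.447902	167052.896317041
posctrl_b01	control	3	226283583.004241	145725.296527013
posctrl_b01	mir	1	25561033.7739148	79784.3116297199
posctrl_b01	mir	2	33496598.7693711	124140.797234809
posctrl_b01	mir	3	37398374.3415159	116858.676155864
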