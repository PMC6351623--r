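# Synthetic example Ct table: unspliced-transcript primer set for one target
# gene and the RNA-polymerase-III-factor reference assay, wild-type vs an
# NMD mutant, three biological x two technical replicates, with
# standard-curve slopes per assay.
assay	sample	group	ct	slope
YRA1_unspliced	wt_1	wt	27.10	-3.32
YRA1_unspliced	wt_1	wt	27.18	-3.32
YRA1_unspliced	wt_2	wt	27.35	-3.32
YRA1_unspliced	wt_2	wt	27.29	-3.32
YRA1_unspliced	wt_3	wt	26.92	-3.32
YRA1_unspliced	wt_3	wt	27.01	-3.32
YRA1_unspliced	upf1_1	upf1	22.40	-3.32
YRA1_unspliced	upf1_1	upf1	22.52	-3.32
YRA1_unspliced	upf1_2	upf1	22.18	-3.32
YRA1_unspliced	upf1_2	upf1	22.25	-3.32
YRA1_unspliced	upf1_3	upf1	22.61	-3.32
YRA1_unspliced	upf1_3	upf1	22.70	-3.32
TFC1	wt_1	wt	24.50	-3.45
TFC1	wt_1	wt	24.55	-3.45
TFC1	wt_2	wt	24.61	-3.45
TFC1	wt_2	wt	24.58	-3.45
TFC1	wt_3	wt	24.47	-3.45
TFC1	wt_3	wt	24.44	-3.45
TFC1	upf1_1	upf1	24.70	-3.45
TFC1	upf1_1	upf1	24.66	-3.45
TFC1	upf1_2	upf1	24.52	-3.45
TFC1	upf1_2	upf1	24.49	-3.45
TFC1	upf1_3	upf1	24.80	-3.45
TFC1	upf1_3	upf1	24.74	-3.45
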