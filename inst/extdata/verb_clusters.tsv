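activate	1	11	111
stimulate	1	11	111
induce	1	11	112
increase	1	12	121
elevate	1	12	121
raise	1	12	122
affect	1	13	131
alter	1	13	131
associate	1	14	141
correlate	1	14	141
inhibit	2	21	211
halt	2	21	211
slow	2	21	212
decrease	2	22	221
reduce	2	22	221
lower	2	22	222
measure	3	31	311
assess	3	31	311
quantify	3	31	312
detect	3	31	313
analyze	3	32	321
examine	3	32	321
evaluate	3	32	322
expose	3	33	331
ingest	3	33	332
inhale	3	33	332
absorb	3	33	333
report	3	34	341
observe	3	34	342
collect	3	34	343
contain	3	35	351
exceed	3	35	352
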