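gene_id	scramble_fold	fold_change	significant
LAMC2	1.00	0.46	TRUE
ZDHHC21	1.00	0.95	FALSE
TGIF2	1.00	0.21	TRUE
SPRY4	1.00	0.55	TRUE
MAPK10	1.00	1.50	FALSE
AKT3	1.00	0.80	TRUE
MAP2K6	1.00	0.48	TRUE
CDK6	1.00	0.20	TRUE
GSK3B	1.00	1.11	FALSE
CREB5	1.00	0.50	TRUE
FOS	1.00	0.41	TRUE
RPS6KA3	1.00	0.98	FALSE
E2F7	1.00	0.28	TRUE
KPNA1	1.00	1.00	FALSE
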