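metric	forest	grassland	crop	vineyards
links	16430.8	5846.4	4122.6	2046.7
positive_links	12042.4	4539.5	3101.2	1794.0
negative_links	4388.4	1306.8	1021.4	342.7
pn_ratio	2.9	3.7	3.5	5.5
connectance	0.008	0.003	0.002	0.001
avg_path_length	0.139	0.129	0.116	0.080
avg_degree	16.2	5.8	4.1	1.0
richness_otu	1083.3	1238.1	1305.9	1342.8
shannon_otu	5.27	5.41	5.50	5.57
evenness_otu	0.18	0.18	0.19	0.19
richness_genus	284.6	333.4	360.2	359.5
shannon_genus	4.04	4.19	4.25	4.26
evenness_genus	0.21	0.20	0.20	0.20
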