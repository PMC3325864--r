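gene_symbol	fold_enrichment	are_count
ZNF184	39.636307	0
C7orf38	36.77381	0
ZNF14	36.34539	0
MYC	33.380974	0
KLF10	31.022799	0
ZNF624	30.735386	0
KIAA1383	27.78753	0
WDR5B	24.241896	0
ZNF443	24.03738	0
ZNF606	23.884226	0
EGR3	22.023645	0
ZNF750	21.599466	0
ZBTB6	21.308832	1
ZNF367	20.524889	2
ZNF44	18.437605	0
ZNF658	18.434893	0
NFKBIA	17.987656	1
FEM1C	17.382252	0
FAM5B	17.253944	1
TRAF6	17.018587	0
ZNF319	16.993372	0
NUAK2	16.958181	4
ZNF564	16.866674	0
EXOC8	16.58628	3
HIST1H4B	16.585716	0
ZNF217	16.54123	1
ZBED5	16.376629	0
PNRC1	16.23357	0
THAP6	16.157799	1
PTGER4	16.002222	0
ZIC5	15.810935	1
TRIB1	15.656507	0
KIAA1586	15.557861	0
PLEKHF2	14.738077	0
ZNF643	14.671463	0
ZNF267	14.121434	1
EGR1	13.995536	0
ZNF709	13.961123	1
SOCS3	13.905058	2
TIPARP	13.888878	4
CDCA4	13.859092	1
FOS	13.489109	2
ZNF764	13.478119	4
PLK2	13.028596	2
DLC1	12.873251	0
ELF2	12.868533	0
ZNF773	12.810777	0
PPP1R3B	12.796747	0
SOCS6	12.379617	1
NRIP1	12.327525	0
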