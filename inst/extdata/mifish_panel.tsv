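probe	cytoband	chromosome	position	group
CCP10	10p11.1	chr10	39800000	1
COX2	1q31.1	chr1	186700000	1
PIK3CA	3q26.32	chr3	179200000	1
FBXW7	4q31.3	chr4	152400000	1
CCNB1	5q13.2	chr5	69200000	1
DBC2	8p21.3	chr8	23000000	2
MYC	8q24.21	chr8	127700000	2
CDKN2A	9p21.3	chr9	22000000	2
PTEN	10q23.31	chr10	87900000	2
CCND1	11q13.3	chr11	69600000	2
KRAS	12p12.1	chr12	25200000	3
RB1	13q14.2	chr13	48300000	3
CDH1	16q22.1	chr16	68700000	3
TP53	17p13.1	chr17	7700000	3
NF1	17q11.2	chr17	31100000	3
HER2	17q12	chr17	39700000	4
SMAD4	18q21.2	chr18	51000000	4
CCNE1	19q12	chr19	29800000	4
ZNF217	20q13.2	chr20	53600000	4
NF2	22q12.2	chr22	29600000	4
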