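gene	status	class	hla	classical	map_index	merged_map_group
DPB2	pseudogene	II	TRUE	FALSE	1
DPA2	pseudogene	II	TRUE	FALSE	2
DPB1	expressed	II	TRUE	TRUE	3
DPA1	expressed	II	TRUE	TRUE	4
DOA	expressed	II	TRUE	FALSE	5
DMA	expressed	II	TRUE	FALSE	6
DMB	expressed	II	TRUE	FALSE	7
DOB	expressed	II	TRUE	FALSE	8
TAP2	expressed	other	FALSE	FALSE	9
TAP1	expressed	other	FALSE	FALSE	10
DQB2	expressed	II	TRUE	FALSE	11
DQA2	expressed	II	TRUE	FALSE	12
DQB1	expressed	II	TRUE	TRUE	13
DQA1	expressed	II	TRUE	TRUE	14
DRB1	expressed	II	TRUE	TRUE	15
DRB3	expressed	II	TRUE	TRUE	16	DRB3/4/5
DRB4	expressed	II	TRUE	TRUE	16	DRB3/4/5
DRB5	expressed	II	TRUE	TRUE	16	DRB3/4/5
DRB6	pseudogene	II	TRUE	FALSE	17	DRB6/7
DRB7	pseudogene	II	TRUE	FALSE	17	DRB6/7
DRB9	gene_fragment	II	TRUE	FALSE	18
DRA	expressed	II	TRUE	TRUE	19
MICB	expressed	I	FALSE	FALSE	20
MICA	expressed	I	FALSE	FALSE	21
B	expressed	I	TRUE	TRUE	22
C	expressed	I	TRUE	TRUE	23
S	gene_fragment	I	TRUE	FALSE	24
E	expressed	I	TRUE	FALSE	25
T	gene_fragment	I	TRUE	FALSE	26
W	gene_fragment	I	TRUE	FALSE	27
P	gene_fragment	I	TRUE	FALSE	28
U	gene_fragment	I	TRUE	FALSE	29
J	pseudogene	I	TRUE	FALSE	30
L	pseudogene	I	TRUE	FALSE	31
N	gene_fragment	I	TRUE	FALSE	32
A	expressed	I	TRUE	TRUE	33
Y	pseudogene	I	TRUE	FALSE	34
R	gene_fragment	I	TRUE	FALSE	35
H	pseudogene	I	TRUE	FALSE	36
K	pseudogene	I	TRUE	FALSE	37
V	pseudogene	I	TRUE	FALSE	38
G	expressed	I	TRUE	FALSE	39
F	expressed	I	TRUE	FALSE	40
HFE	expressed	I	FALSE	FALSE	41
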