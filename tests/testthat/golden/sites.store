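#TABLE proteins
id	description	sequence
SYN0001	Synthetic fixture protein 1	EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMTEPISQYHPNSAPGTKHWVSMLHWCLAMRLSNHIAWDMAQGYKFQTDDHQDWNTKVT
SYN0002	Synthetic fixture protein 2	RYWSWECSANHKPCCWTCMDDQWPMSIKVLRYFFHFNQGYSRCADKGTYFKNIETKAYLQLGVSCI
SYN0003	Synthetic fixture protein 3	FIHYETLEKKRGGEDDPKHQFHYYLIAQNSNLCTAEFNRQRTRVAILHHMVKYCFMCYDRGKRFQFMMTAPAWESTHGYSCPDLGHTAADMPVFSICEGTKPQKMIDWWAYE
SYN0004	Synthetic fixture protein 4	FLNDDEKDDYKWNVNHEWTFWYKRWFQHPRVGCATPPICKIYQYFLNYRCAFFIPELGVFYAGQPITWSRSTWQGMIYWFCFNDVQPRCPSHSTMKIPG
SYN0005	Synthetic fixture protein 5	AGTPCRENFGWYNDERQPDQRCGWSYEQSFDETRDSSEEYFARFMNYMGSEGYIAIMMTKVWNIGMWFC
1ab1_A	PDB 1ab1 chain A	WCIGRKACKTFLCFQGSFTAIWTYYSTFAACEYGYCRYVDYCRLPSMESRPWSHVAEFQECAWTWPVHEHKI
1ab2_A	PDB 1ab2 chain A	DVDRHAYKQYSNNQSANNVIFNKCKKKMLGCDACWFCKNKVCRPHEGVSPSISQGIDIFQPWDFPWQEYPDILPLGLHVWVQRRLFATP
1ab3_A	PDB 1ab3 chain A	AALPWINMSMGIHDLAFFEMKCLCCNGQKHWFTKNPNDICKSHFHHNNCYYWKYIDSHLWDPSWQWLCSMWDHNIPYVLCKWNLNGIPMPCINWYDENPH
#TABLE annotations
protein_id	source	category	ligand	comment	pdb_chain	evidence	positions
SYN0001	swissprot	active		Nucleophile		ECO:0000269|PubMed:100001	54
SYN0001	swissprot	binding		Zinc		ECO:0000269|PubMed:100001	92
SYN0001	swissprot	binding		Zinc		ECO:0000269|PubMed:100001	112
SYN0001	swissprot	modified				ECO:0000269|PubMed:100001	6,114
SYN0001	swissprot	active		Nucleophile		ECO:0000269|PubMed:100006	63
SYN0001	swissprot	binding		Zinc		ECO:0000269|PubMed:100006	35
SYN0001	swissprot	binding		Zinc		ECO:0000269|PubMed:100006	87
SYN0001	swissprot	mutagenesis		Loss of activity		ECO:0000269|PubMed:100006	11
SYN0002	swissprot	active		Nucleophile		ECO:0000269|PubMed:100002	18
SYN0002	swissprot	binding		Zinc		ECO:0000269|PubMed:100002	27
SYN0002	swissprot	binding		Zinc		ECO:0000269|PubMed:100002	37
SYN0002	swissprot	functional_other		Substrate binding		ECO:0000269|PubMed:100002	41,42,43,44,45,46
SYN0002	biolip	binding	MG	binding to MG	B	2dup	55,58
SYN0003	swissprot	active		Nucleophile		ECO:0000269|PubMed:100003	81
SYN0003	swissprot	binding		Zinc		ECO:0000269|PubMed:100003	60
SYN0003	swissprot	binding		Zinc		ECO:0000269|PubMed:100003	65
SYN0003	swissprot	modified		L -> P: loss of kinase activity		ECO:0000269|PubMed:100003	64
SYN0004	swissprot	active		Nucleophile		ECO:0000269|PubMed:100004	31
SYN0004	swissprot	binding		Zinc		ECO:0000269|PubMed:100004	45
SYN0004	swissprot	binding		Zinc		ECO:0000269|PubMed:100004	95
SYN0005	swissprot	active		Nucleophile		ECO:0000269|PubMed:100005	43
SYN0005	swissprot	binding		Zinc		ECO:0000269|PubMed:100005	32
SYN0005	swissprot	binding		Zinc		ECO:0000269|PubMed:100005	40
1ab1_A	biolip	binding	ZN	binding to ZN	A	1ab1	28,49,52
1ab1_A	biolip	active		active site	A	1ab1	12
1ab2_A	biolip	binding	ZN	binding to ZN	A	1ab2	22,58,70
1ab3_A	biolip	binding	ZN	binding to ZN	A	1ab3	22,56,91
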