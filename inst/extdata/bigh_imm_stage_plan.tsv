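name	scope	method	markers	targets
majors	Leukocytes	two_step	FSC-A,SSC-A,CD45,CD19,CD5,CD27,CD24,CD38	Neutrophils|Eosinophils|Monocytes|CD5+ T-cells|CD5- NK-cells|Other nucleated cells|B-cells
b_compartment	B-cells	two_step	CD19,CD20,CD38,CD24,CD21,CD27,CD45,CD138,IgD,IgM	Pre-GC B-cells|Memory B-cells|Plasma cells
pregc_maturation	Pre-GC B-cells	maturation	CD38,CD5	Immature B-cells|Naive CD5+ B-cells|Naive CD5- B-cells
pc_maturation	Plasma cells	maturation	CD20,CD138	CD20+CD138- PC|CD20-CD138- PC|CD20-CD138+ PC
naive_cd5neg	Naive CD5- B-cells	two_step	CD21,CD24,CD62L	Naive CD5- CD21+ CD62L+ B-cells|Naive CD5- CD21+ CD62L- B-cells|Naive CD5- CD21- CD24+ B-cells|Naive CD5- CD21- CD24- B-cells
mbc_isotype	Memory B-cells	two_step	IgM,IgD,IgG1,IgG2,IgG3,IgG4,IgA1,IgA2	MBC IgMD|MBC IgG1|MBC IgG2|MBC IgG3|MBC IgG4|MBC IgA1|MBC IgA2|MBC IgHneg
mbc_IgMD	MBC IgMD	two_step	CD21,CD20,CD24,CD27	MBC IgMD CD21+CD20+ CD27-|MBC IgMD CD21+CD20+ CD27+|MBC IgMD CD21-CD20++ CD24- CD27-|MBC IgMD CD21-CD20++ CD24- CD27+|MBC IgMD CD21-CD20++ CD24+ CD27-|MBC IgMD CD21-CD20++ CD24+ CD27+
mbc_IgG1	MBC IgG1	two_step	CD21,CD20,CD24,CD27	MBC IgG1 CD21+CD20+ CD27-|MBC IgG1 CD21+CD20+ CD27+|MBC IgG1 CD21-CD20++ CD24- CD27-|MBC IgG1 CD21-CD20++ CD24- CD27+|MBC IgG1 CD21-CD20++ CD24+ CD27-|MBC IgG1 CD21-CD20++ CD24+ CD27+
mbc_IgG2	MBC IgG2	two_step	CD21,CD20,CD24,CD27	MBC IgG2 CD21+CD20+ CD27-|MBC IgG2 CD21+CD20+ CD27+|MBC IgG2 CD21-CD20++ CD24- CD27-|MBC IgG2 CD21-CD20++ CD24- CD27+|MBC IgG2 CD21-CD20++ CD24+ CD27-|MBC IgG2 CD21-CD20++ CD24+ CD27+
mbc_IgG3	MBC IgG3	two_step	CD21,CD20,CD24,CD27	MBC IgG3 CD21+CD20+ CD27-|MBC IgG3 CD21+CD20+ CD27+|MBC IgG3 CD21-CD20++ CD24- CD27-|MBC IgG3 CD21-CD20++ CD24- CD27+|MBC IgG3 CD21-CD20++ CD24+ CD27-|MBC IgG3 CD21-CD20++ CD24+ CD27+
mbc_IgG4	MBC IgG4	two_step	CD21,CD20,CD24,CD27	MBC IgG4 CD21+CD20+ CD27-|MBC IgG4 CD21+CD20+ CD27+|MBC IgG4 CD21-CD20++ CD24- CD27-|MBC IgG4 CD21-CD20++ CD24- CD27+|MBC IgG4 CD21-CD20++ CD24+ CD27-|MBC IgG4 CD21-CD20++ CD24+ CD27+
mbc_IgA1	MBC IgA1	two_step	CD21,CD20,CD24,CD27	MBC IgA1 CD21+CD20+ CD27-|MBC IgA1 CD21+CD20+ CD27+|MBC IgA1 CD21-CD20++ CD24- CD27-|MBC IgA1 CD21-CD20++ CD24- CD27+|MBC IgA1 CD21-CD20++ CD24+ CD27-|MBC IgA1 CD21-CD20++ CD24+ CD27+
mbc_IgA2	MBC IgA2	two_step	CD21,CD20,CD24,CD27	MBC IgA2 CD21+CD20+ CD27-|MBC IgA2 CD21+CD20+ CD27+|MBC IgA2 CD21-CD20++ CD24- CD27-|MBC IgA2 CD21-CD20++ CD24- CD27+|MBC IgA2 CD21-CD20++ CD24+ CD27-|MBC IgA2 CD21-CD20++ CD24+ CD27+
mbc_IgHneg	MBC IgHneg	two_step	CD21,CD20,CD24,CD27	MBC IgHneg CD21+CD20+ CD27-|MBC IgHneg CD21+CD20+ CD27+|MBC IgHneg CD21-CD20++ CD24- CD27-|MBC IgHneg CD21-CD20++ CD24- CD27+|MBC IgHneg CD21-CD20++ CD24+ CD27-|MBC IgHneg CD21-CD20++ CD24+ CD27+
pc_CD20CD138PC	CD20+CD138- PC	two_step	IgM,IgD,IgG1,IgG2,IgG3,IgG4,IgA1,IgA2	CD20+CD138- PC IgMD|CD20+CD138- PC IgG1|CD20+CD138- PC IgG2|CD20+CD138- PC IgG3|CD20+CD138- PC IgG4|CD20+CD138- PC IgA1|CD20+CD138- PC IgA2|CD20+CD138- PC IgHneg
pc_CD20CD138PC	CD20-CD138- PC	two_step	IgM,IgD,IgG1,IgG2,IgG3,IgG4,IgA1,IgA2	CD20-CD138- PC IgMD|CD20-CD138- PC IgG1|CD20-CD138- PC IgG2|CD20-CD138- PC IgG3|CD20-CD138- PC IgG4|CD20-CD138- PC IgA1|CD20-CD138- PC IgA2|CD20-CD138- PC IgHneg
pc_CD20CD138PC	CD20-CD138+ PC	two_step	IgM,IgD,IgG1,IgG2,IgG3,IgG4,IgA1,IgA2	CD20-CD138+ PC IgMD|CD20-CD138+ PC IgG1|CD20-CD138+ PC IgG2|CD20-CD138+ PC IgG3|CD20-CD138+ PC IgG4|CD20-CD138+ PC IgA1|CD20-CD138+ PC IgA2|CD20-CD138+ PC IgHneg
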