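tissue	omics_tag	class_label	full	matched	unmatched	matched_balanced	unmatched_balanced
PBMC	proteomic	AH	20	18	2	9	11
PBMC	proteomic	CT	22	19	3	12	10
PBMC	proteomic	AC	13	13	0	6	7
PBMC	transcriptomic	AH	38	18	20	9	29
PBMC	transcriptomic	CT	20	19	1	12	8
PBMC	transcriptomic	AC	40	13	27	6	34
liver	proteomic	AH	33	29	4	24	9
liver	proteomic	CT	10	3	7	3	7
liver	proteomic	AC	10	5	5	3	7
liver	transcriptomic	AH	32	29	3	24	8
liver	transcriptomic	CT	8	3	5	3	5
liver	transcriptomic	AC	8	5	3	3	5
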