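panel	modality	feature_id
osteoporosis	microbiota	Klebsiella
osteoporosis	microbiota	Veillonella
osteoporosis	microbiota	Intestinibacter
osteoporosis	metabolite	9E-tetradecenoic acid
osteoporosis	metabolite	Suberic acid
subtype	methylation	cg22026953
subtype	methylation	cg18008345
subtype	methylation	cg21813369
subtype	methylation	cg11070274
subtype	methylation	cg00329101
subtype	methylation	cg23088318
subtype	methylation	cg15508935
subtype	methylation	cg09656629
subtype	methylation	cg15320980
subtype	methylation	cg00431894
subtype	methylation	cg18243574
subtype	microbiota	Klebsiella
subtype	microbiota	Streptococcus
subtype	microbiota	Veillonella
subtype	metabolite	Threonic acid
subtype	metabolite	5Z-Dodecenoic acid
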