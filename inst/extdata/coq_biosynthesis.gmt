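CoQ_biosynthesis	Coenzyme Q (ubiquinone) biosynthesis, curated membership	Hpd	Tat	Coq2	Coq3	Coq4	Coq5	Coq6	Coq7	Coq9	Adck3	Adck4
Terpenoid_backbone_biosynthesis	Mevalonate pathway example members	Hmgcr	Hmgcs1	Mvk	Pmvk	Mvd	Idi1	Fdps	Ggps1
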