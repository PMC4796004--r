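regulator	regulator_gene	mechanism	effector	effector_category	sign	target_gene
PerR	perR	TF+M	Hydrogen peroxide	biochemical	induced	hemL
PerR	perR	TF+M	Hydrogen peroxide	biochemical	induced	hemB
PerR	perR	TF+M	Hydrogen peroxide	biochemical	induced	hemD
PerR	perR	TF+M	Hydrogen peroxide	biochemical	induced	hemC
PerR	perR	TF+M	Hydrogen peroxide	biochemical	induced	hemX
PerR	perR	TF+M	Hydrogen peroxide	biochemical	induced	hemA
Zur	zur	TF+M	Zinc	biochemical	repressed	znuA
CcpA	ccpA	TF+PP+M	D-fructose-1,6-bisphosphate	biochemical	unknown	treP
CcpA	ccpA	TF+PP+M	Glucose-6-Phosphate	biochemical	unknown	treP
CcpA	ccpA	TF+PP+M	phosphate	biochemical	unknown	treP
TreR	treR	TF+M	D-trehalose-6-phosphate	biochemical	induced	treP
CcpA	ccpA	TF+PP+M	D-fructose-1,6-bisphosphate	biochemical	unknown	treA
CcpA	ccpA	TF+PP+M	Glucose-6-Phosphate	biochemical	unknown	treA
CcpA	ccpA	TF+PP+M	phosphate	biochemical	unknown	treA
TreR	treR	TF+M	D-trehalose-6-phosphate	biochemical	induced	treA
CcpA	ccpA	TF+PP+M	D-fructose-1,6-bisphosphate	biochemical	unknown	treR
CcpA	ccpA	TF+PP+M	Glucose-6-Phosphate	biochemical	unknown	treR
CcpA	ccpA	TF+PP+M	phosphate	biochemical	unknown	treR
TreR	treR	TF+M	D-trehalose-6-phosphate	biochemical	induced	treR
Spx	spx	TF+S	Disulfide_stress_conditions	environmental	induced	yfkO
Fur	fur	TF+M	Iron	biochemical	repressed	yclN
Fur	fur	TF+M	Iron	biochemical	repressed	yclO
Fur	fur	TF+M	Iron	biochemical	repressed	yclP
Fur	fur	TF+M	Iron	biochemical	repressed	yclQ
Fur	fur	TF+M	Iron	biochemical	repressed	yfmF
Fur	fur	TF+M	Iron	biochemical	repressed	yfmE
Fur	fur	TF+M	Iron	biochemical	repressed	yfmD
Fur	fur	TF+M	Iron	biochemical	repressed	yfmC
Fur	fur	TF+M	Iron	biochemical	repressed	yhfQ
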