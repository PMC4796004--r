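regulator	regulator_gene	mechanism	effector	effector_category	sign	target_gene
	 	 	D-fructose-1,6-bisphosphate	biochemical	induced	ywdA
	 	 	Glucose-6-Phosphate	biochemical	induced	ywdA
	 	 	Sucrose	biochemical	induced	ywdA
	 	 	D-fructose-1,6-bisphosphate	biochemical	induced	sacA
	 	 	Glucose-6-Phosphate	biochemical	induced	sacA
	 	 	Sucrose	biochemical	induced	sacA
	 	 	D-fructose-1,6-bisphosphate	biochemical	induced	sacP
	 	 	Glucose-6-Phosphate	biochemical	induced	sacP
	 	 	Sucrose	biochemical	induced	sacP
	 	 	uncharacterized-1	biochemical	induced	sacX
	 	 	Sucrose	biochemical	induced	sacX
	 	 	uncharacterized-1	biochemical	induced	sacY
	 	 	Sucrose	biochemical	induced	sacY
	 	 	uncharacterized-2	biochemical	induced	sacB
	 	 	uncharacterized-3	biochemical	induced	sacB
	 	 	Sucrose	biochemical	induced	sacB
	 	 	uncharacterized-2	biochemical	induced	levB
	 	 	uncharacterized-3	biochemical	induced	levB
	 	 	Sucrose	biochemical	induced	levB
	 	 	uncharacterized-2	biochemical	induced	yveA
	 	 	uncharacterized-3	biochemical	induced	yveA
	 	 	uncharacterized-4	biochemical	induced	yveA
	 	 	Sucrose	biochemical	induced	yveA
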