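RxCUI	DrugName	hasMOA	ConceptName	DoseForm
207371	Minoxidil	Potassium Channel Interactions	Minoxidil 20 MG/ML Topical Solution (Rogaine)	Topical solution
208560	Timolol	Adrenergic beta1-Antagonists	Timolol 2.5 MG/ML Ophthalmic Solution (Betimol)	Ophthalmic solution
213729	Betaxolol	Adrenergic beta1-Antagonists	Betaxolol 2.5 MG/ML Ophthalmic Suspension (Betoptic S)	Ophthalmic suspension
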