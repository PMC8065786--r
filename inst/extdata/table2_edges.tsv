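direction	roi_a_name	roi_a_abbrev	roi_b_name	roi_b_abbrev	p_value
Mathematicians > Non-mathematicians	Left lateral orbital gyrus	LOrG.L	Left triangular part of the inferior frontal gyrus	TrIFG.L	0.0003
Mathematicians > Non-mathematicians	Right ventral diencephalon	VDc.R	Right frontal pole	FP.R	0.0011
Mathematicians > Non-mathematicians	Left ventral diencephalon	VDc.L	Left superior frontal gyrus	SFG.L	0.0019
Mathematicians > Non-mathematicians	Left caudate nucleus	CN.L	Right opercular part of the inferior frontal gyrus	OpIFG.R	0.0021
Mathematicians > Non-mathematicians	Left parahippocampal gyrus	PhG.L	Right supplementary motor cortex	SMC.R	0.0031
Mathematicians > Non-mathematicians	Left caudate nucleus	CN.L	Right inferior occipital gyrus	IOG.R	0.0039
Mathematicians > Non-mathematicians	Right pallidum	Pd.R	Left inferior temporal gyrus	ITG.L	0.0039
Mathematicians > Non-mathematicians	Left middle cingulate gyrus	MCG.L	Right temporal pole	TP.R	0.0039
Mathematicians > Non-mathematicians	Left putamen	Pu.L	Left frontal pole	FP.L	0.0041
Mathematicians > Non-mathematicians	Right orbital part of the inferior frontal gyrus	OrIFG.R	Left planum temporale	PT.L	0.0041
Mathematicians > Non-mathematicians	Left putamen	Pu.L	Left inferior temporal gyrus	ITG.L	0.0051
Mathematicians > Non-mathematicians	Left ventral diencephalon	VDc.L	Right frontal pole	FP.R	0.0051
Mathematicians > Non-mathematicians	Right postcentral gyrus	PcG.R	Left precentral gyrus	PrG.L	0.0059
Mathematicians > Non-mathematicians	Left fusiform gyrus	FuG.L	Left planum temporale	PT.L	0.0061
Mathematicians > Non-mathematicians	Left anterior orbital gyrus	AOrG.L	Left occipital pole	OP.L	0.0061
Mathematicians > Non-mathematicians	Right putamen	Pu.R	Left frontal pole	FP.L	0.0063
Mathematicians > Non-mathematicians	Left lateral orbital gyrus	LOrG.L	Right triangular part of the inferior frontal gyrus	TrIFG.R	0.0065
Mathematicians > Non-mathematicians	Left frontal pole	FP.L	Left posterior orbital gyrus	POrG.L	0.0065
Mathematicians > Non-mathematicians	Right occipital pole	OP.R	Right planum temporale	PT.R	0.0069
Mathematicians > Non-mathematicians	Right putamen	Pu.R	Right medial orbital gyrus	MOrG.R	0.0073
Mathematicians > Non-mathematicians	Left amygdala	Amg.L	Right medial frontal cortex	MFC.R	0.0079
Mathematicians > Non-mathematicians	Right middle temporal gyrus	MTG.R	Left temporal pole	TP.L	0.0081
Non-Mathematicians > Mathematicians	Left lateral orbital gyrus	LOrG.L	Right precuneus	Pcun.R	0.000
Non-Mathematicians > Mathematicians	Right thalamus	Th.R	Right lateral orbital gyrus	LOrG.R	0.0007
Non-Mathematicians > Mathematicians	Left thalamus	Th.L	Right lateral orbital gyrus	LOrG.R	0.0011
Non-Mathematicians > Mathematicians	Right middle occipital gyrus	MOG.R	Right supplementary motor cortex	SMC.R	0.0017
Non-Mathematicians > Mathematicians	Right middle occipital gyrus	MOG.R	Left middle occipital gyrus	MOG.L	0.0021
Non-Mathematicians > Mathematicians	Left gyrus rectus	GRe.L	Right precuneus	Pcun.R	0.0027
Non-Mathematicians > Mathematicians	Right postcentral gyrus	PcG.R	Right superior occipital gyrus	SOG.R	0.0031
Non-Mathematicians > Mathematicians	Right medial frontal cortex	MFC.R	Right precuneus	Pcun.R	0.0033
Non-Mathematicians > Mathematicians	Right caudate nucleus	CN.R	Right planum temporale	PT.R	0.0037
Non-Mathematicians > Mathematicians	Left medial frontal cortex	MFC.L	Right precuneus	Pcun.R	0.0041
Non-Mathematicians > Mathematicians	Right ventral diencephalon	VDc.R	Right fusiform gyrus	FuG.R	0.0050
Non-Mathematicians > Mathematicians	Right caudate nucleus	CN.R	Left middle cingulate gyrus	MCG.L	0.0053
Non-Mathematicians > Mathematicians	Left lateral orbital gyrus	LOrG.L	Left precuneus	Pcun.L	0.0061
Non-Mathematicians > Mathematicians	Right caudate nucleus	CN.R	Left anterior insula	AIns.L	0.0067
Non-Mathematicians > Mathematicians	Right lingual gyrus	LiG.R	Left lingual gyrus	LiG.L	0.0067
Non-Mathematicians > Mathematicians	Left precentral gyrus	PrG.L	Left middle temporal gyrus	MTG.L	0.0069
Non-Mathematicians > Mathematicians	Left inferior temporal gyrus	ITG.L	Left precentral gyrus	PrG.L	0.0069
Non-Mathematicians > Mathematicians	Left ventral diencephalon	VDc.L	Right fusiform gyrus	FuG.R	0.0075
Non-Mathematicians > Mathematicians	Right gyrus rectus	GRe.R	Right precuneus	Pcun.R	0.0081
Non-Mathematicians > Mathematicians	Right hippocampus	Hi.R	Right inferior occipital gyrus	IOG.R	0.0089
Non-Mathematicians > Mathematicians	Right caudate nucleus	CN.R	Right supramarginal gyrus	SMG.R	0.0091
Non-Mathematicians > Mathematicians	Right caudate nucleus	CN.R	Left caudate nucleus	CN.L	0.0093
Non-Mathematicians > Mathematicians	Right calcarine cortex	Calc.R	Right lingual gyrus	LiG.R	0.0099
Non-Mathematicians > Mathematicians	Right frontal pole	FP.R	Right posterior orbital gyrus	POrG.R	0.0099
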