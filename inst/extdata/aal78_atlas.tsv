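label	hemisphere	region
PreCG-L	L	Left Precentral Gyrus
PreCG-R	R	Right Precentral Gyrus
SFGdor-L	L	Left Superior Frontal Gyrus (dorsal)
SFGdor-R	R	Right Superior Frontal Gyrus (dorsal)
ORBsupb-L	L	Left Orbitofrontal Cortex (superior)
ORBsupb-R	R	Right Orbitofrontal Cortex (superior)
MFG-L	L	Left Middle Frontal Gyrus
MFG-R	R	Right Middle Frontal Gyrus
ORBmid-L	L	Left Orbitofrontal Cortex (middle)
ORBmid-R	R	Right Orbitofrontal Cortex (middle)
IFGoperc-L	L	Left Inferior Frontal Gyrus (opercular)
IFGoperc-R	R	Right Inferior Frontal Gyrus (opercular)
IFGtriang-L	L	Left Inferior Frontal Gyrus (triangular)
IFGtriang-R	R	Right Inferior Frontal Gyrus (triangular)
ORBinf-L	L	Left Orbitofrontal Cortex (inferior)
ORBinf-R	R	Right Orbitofrontal Cortex (inferior)
ROL-L	L	Left Rolandic Operculum
ROL-R	R	Right Rolandic Operculum
SMA-L	L	Left Supplementary Motor Area
SMA-R	R	Right Supplementary Motor Area
OLF-L	L	Left Olfactory
OLF-R	R	Right Olfactory
SFGmed-L	L	Left Superior Frontal Gyrus (medial)
SFGmed-R	R	Right Superior Frontal Gyrus (medial)
ORBmed-L	L	Left Orbitofrontal Cortex (medial)
ORBmed-R	R	Right Orbitofrontal Cortex (medial)
REC-L	L	Left Rectus Gyrus
REC-R	R	Right Rectus Gyrus
INS-L	L	Left Insula
INS-R	R	Right Insula
ACG-L	L	Left Anterior Cingulate Gyrus
ACG-R	R	Right Anterior Cingulate Gyrus
MCG-L	L	Left Middle Cingulate Gyrus
MCG-R	R	Right Middle Cingulate Gyrus
PCG-L	L	Left Posterior Cingulate Gyrus
PCG-R	R	Right Posterior Cingulate Gyrus
PHG-L	L	Left ParaHippocampal Gyrus
PHG-R	R	Right ParaHippocampal Gyrus
CAL-L	L	Left Calcarine Cortex
CAL-R	R	Right Calcarine Cortex
CUN-L	L	Left Cuneus
CUN-R	R	Right Cuneus
LING-L	L	Left Lingual Gyrus
LING-R	R	Right Lingual Gyrus
SOG-L	L	Left Superior Occipital Gyrus
SOG-R	R	Right Superior Occipital Gyrus
MOG-L	L	Left Middle Occipital Gyrus
MOG-R	R	Right Middle Occipital Gyrus
IOG-L	L	Left Inferior Occipital Gyrus
IOG-R	R	Right Inferior Occipital Gyrus
FFG-L	L	Left Fusiform Gyrus
FFG-R	R	Right Fusiform Gyrus
PoCG-L	L	Left Postcentral Gyrus
PoCG-R	R	Right Postcentral Gyrus
SPG-L	L	Left Superior Parietal Gyrus
SPG-R	R	Right Superior Parietal Gyrus
IPL-L	L	Left Inferior Parietal Lobule
IPL-R	R	Right Inferior Parietal Lobule
SMG-L	L	Left Supramarginal Gyrus
SMG-R	R	Right Supramarginal Gyrus
ANG-L	L	Left Angular Gyrus
ANG-R	R	Right Angular Gyrus
PCUN-L	L	Left Precuneus
PCUN-R	R	Right Precuneus
PCL-L	L	Left Paracentral Lobule
PCL-R	R	Right Paracentral Lobule
HES-L	L	Left Heschl Gyrus
HES-R	R	Right Heschl Gyrus
STG-L	L	Left Superior Temporal Gyrus
STG-R	R	Right Superior Temporal Gyrus
TPOsup-L	L	Left Temporal Pole (superior)
TPOsup-R	R	Right Temporal Pole (superior)
MTG-L	L	Left Middle Temporal Gyrus
MTG-R	R	Right Middle Temporal Gyrus
TPOmid-L	L	Left Temporal Pole (middle)
TPOmid-R	R	Right Temporal Pole (middle)
ITG-L	L	Left Inferior Temporal Gyrus
ITG-R	R	Right Inferior Temporal Gyrus
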