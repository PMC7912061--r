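sequence	activity_class	source
YG	ACE-inhibitory	Drevet (Helix aspersa)
YA	ACE-inhibitory	Drevet (Helix aspersa)
VY	ACE-inhibitory	Drevet (Helix aspersa)
FG	ACE-inhibitory	Drevet (Helix aspersa)
GF	ACE-inhibitory	Drevet (Helix aspersa)
DF	ACE-inhibitory	Drevet (Helix aspersa)
SF	ACE-inhibitory	Drevet (Helix aspersa)
VW	ACE-inhibitory	Drevet (Helix aspersa)
HTYHEVTKH	antioxidant	Babylonia areolata hydrolysate
WPVLAYHFT	antioxidant	Babylonia areolata hydrolysate
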