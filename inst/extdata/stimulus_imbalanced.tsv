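source	target	valence	label
Alyssa	Felix	-1	
Alyssa	Henry	+1	
Alyssa	James	+1	
Alyssa	Nora	+1	
Anne	Henry	+1	
Catherine	Lewis	+1	
Catherine	Marcus	-1	
Catherine	Peter	+1	
Catherine	Sophia	+1	
Elizabeth	Henry	+1	
Elizabeth	James	+1	
Henry	James	+1	
Isabelle	Marcus	+1	
Isabelle	Victoria	+1	
Lewis	Marcus	+1	
Lewis	Oliver	-1	
Lewis	Peter	-1	
Lewis	Sophia	+1	
Marcus	Peter	+1	
Oliver	Peter	-1	
Oliver	Victoria	-1	
Peter	Sophia	-1	
Sophia	Victoria	-1	
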