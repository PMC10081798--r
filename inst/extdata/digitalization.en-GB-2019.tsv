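word	include	exclusion_reason	notes	inflections
digitalization	true	none		digitalization
computer	true	none		computer,computers
internet	true	none		internet
software	true	none		software
automation	true	none		automation
smartphone	true	none		smartphone,smartphones
online	true	none		online
robot	true	none		robot,robots
algorithm	true	none		algorithm,algorithms
platform	false	broader_semantic	thesaurus synonym with broader meaning
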