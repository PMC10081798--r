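word	include	exclusion_reason	notes	inflections
depression	true	none		depression,depressions
sadness	true	none		sadness
melancholy	true	none		melancholy
despair	true	none		despair,despairs,despaired
hopelessness	true	none		hopelessness
apathy	true	none		apathy
fatigue	true	none		fatigue,fatigues
gloom	true	none		gloom
low	false	double_meaning	dominant spatial sense
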