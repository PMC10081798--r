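word	include	exclusion_reason	notes	inflections
anxiety	true	none		anxiety,anxieties
fear	true	none		fear,fears,feared,fearing
worry	true	none		worry,worries,worried,worrying
panic	true	none		panic,panics,panicked
phobia	true	none		phobia,phobias
dread	true	none		dread,dreads,dreaded
unease	true	none		unease
nervousness	true	none		nervousness
interest	false	broader_semantic	thesaurus synonym with broader meaning
concern	false	double_meaning	flagged by native speakers (business sense)
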