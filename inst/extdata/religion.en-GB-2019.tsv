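word	include	exclusion_reason	notes	inflections
God	true	none		God,Gods
Angel	true	none		Angel,Angels
Clergy	true	none		Clergy
Prayer	true	none		Prayer,Prayers
faith	true	none		faith,faiths
worship	true	none		worship,worships,worshipped
temple	true	none		temple,temples
priest	true	none		priest,priests
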