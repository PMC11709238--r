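a	b	c	k	group
healthy	employable	psychosis	10	employability
healthy	employable	depression	10	employability
healthy	employable	anxiety_disorder	10	employability
healthy	reliable	psychosis	10	employability
healthy	reliable	depression	10	employability
healthy	reliable	anxiety_disorder	10	employability
healthy	competent	psychosis	10	employability
healthy	competent	depression	10	employability
healthy	competent	anxiety_disorder	10	employability
healthy	resilient	psychosis	10	employability
healthy	resilient	depression	10	employability
healthy	resilient	anxiety_disorder	10	employability
healthy	lawyer	psychosis	10	professions
healthy	doctor	psychosis	10	professions
healthy	surgeon	psychosis	10	professions
healthy	engineer	psychosis	10	professions
healthy	banker	psychosis	10	professions
healthy	CEO	psychosis	10	professions
woman	doctor	man	10	controls
man	doctor	woman	10	controls
man	lawyer	woman	10	controls
Tokyo	Japan	London	10	controls
London	Japan	Tokyo	10	controls
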