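EPH_EPHRIN_COMPONENTS_SYNTHETIC	synthetic stand-in gene set of EPH-Ephrin signaling component names for examples and tests	EFNA1	EFNA5	EPHA4	EPHA5	EPHA7	EPHB1	EPHB2	EFNB1
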