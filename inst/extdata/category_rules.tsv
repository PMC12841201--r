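order	match_kind	pattern	category
1	prefix	K70	alcohol
2	prefix	F10	alcohol
3	substring	alcohol	alcohol
4	substring	delivery	developmental
5	substring	liver	liver
6	substring	gamma glutamyltransferase	liver
7	substring	lipid	liver
8	substring	cholesterol	liver
9	substring	triglyceride	liver
10	fallthrough	*	developmental
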