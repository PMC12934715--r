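cell_type	name	value
E	coef_1	-48.9356363695993
E	coef_2	1.50444078806799
E	coef_3	4.95625320959338
E	coef_4	-0.694074074495617
E	coef_5	-0.449099404551452
E	coef_6	2.93709530095398
E	coef_7	1.28357658606068
E	coef_8	-9.42754203883827
E	coef_9	-0.686018508681154
E	coef_10	9.28053919422294
E	dom_1	0
E	dom_2	30
E	dom_3	0
E	dom_4	60
E	dom_5	0
E	dom_6	100
I	coef_1	-53.2257853729085
I	coef_2	10.0383069353837
I	coef_3	-46.4013522395451
I	coef_4	8.66782086743094
I	coef_5	-5.82893803232984
I	coef_6	-62.2261577367912
I	coef_7	-50.8275033508251
I	coef_8	15.0532729656861
I	coef_9	5.14766036083225
I	coef_10	-37.831632993753
I	dom_1	0
I	dom_2	30
I	dom_3	0
I	dom_4	60
I	dom_5	0
I	dom_6	1
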