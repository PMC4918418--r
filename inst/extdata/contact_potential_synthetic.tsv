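# Synthetic pairwise contact potential (units kT): hydrophobic-product attraction + charge term + background.
# Constructed stand-in with the qualitative structure of knowledge-based contact potentials; not a published table.
A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
-1.18	-1.288889	-0.355556	-0.355556	-1.335556	-0.837778	-0.402222	-1.6	-0.293333	-1.491111	-1.195556	-0.355556	-0.651111	-0.355556	-0.2	-0.775556	-0.791111	-1.553333	-0.76	-0.697778
-1.288889	-1.409877	-0.37284	-0.37284	-1.461728	-0.908642	-0.424691	-1.755556	-0.303704	-1.634568	-1.306173	-0.37284	-0.701235	-0.37284	-0.2	-0.839506	-0.85679	-1.703704	-0.822222	-0.753086
-0.355556	-0.37284	0.575309	0.575309	-0.380247	-0.301235	-0.632099	-0.422222	-1.014815	-0.404938	-0.358025	-0.224691	-0.271605	-0.224691	-1	-0.291358	-0.293827	-0.414815	-0.288889	-0.279012
-0.355556	-0.37284	0.575309	0.575309	-0.380247	-0.301235	-0.632099	-0.422222	-1.014815	-0.404938	-0.358025	-0.224691	-0.271605	-0.224691	-1	-0.291358	-0.293827	-0.414815	-0.288889	-0.279012
-1.335556	-1.461728	-0.380247	-0.380247	-1.515802	-0.939012	-0.434321	-1.822222	-0.308148	-1.696049	-1.35358	-0.380247	-0.722716	-0.380247	-0.2	-0.866914	-0.884938	-1.768148	-0.848889	-0.77679
-0.837778	-0.908642	-0.301235	-0.301235	-0.939012	-0.615062	-0.331605	-1.111111	-0.260741	-1.040247	-0.847901	-0.301235	-0.49358	-0.301235	-0.2	-0.574568	-0.584691	-1.080741	-0.564444	-0.523951
-0.402222	-0.424691	-0.632099	-0.632099	-0.434321	-0.331605	-0.041728	-0.488889	0.180741	-0.46642	-0.405432	-0.232099	-0.293086	-0.232099	0.2	-0.318765	-0.321975	-0.479259	-0.315556	-0.302716
-1.6	-1.755556	-0.422222	-0.422222	-1.822222	-1.111111	-0.488889	-2.2	-0.333333	-2.044444	-1.622222	-0.422222	-0.844444	-0.422222	-0.2	-1.022222	-1.044444	-2.133333	-1	-0.911111
-0.293333	-0.303704	-1.014815	-1.014815	-0.308148	-0.260741	0.180741	-0.333333	0.591111	-0.322963	-0.294815	-0.214815	-0.242963	-0.214815	0.6	-0.254815	-0.256296	-0.328889	-0.253333	-0.247407
-1.491111	-1.634568	-0.404938	-0.404938	-1.696049	-1.040247	-0.46642	-2.044444	-0.322963	-1.900988	-1.511605	-0.404938	-0.794321	-0.404938	-0.2	-0.958272	-0.978765	-1.982963	-0.937778	-0.855802
-1.195556	-1.306173	-0.358025	-0.358025	-1.35358	-0.847901	-0.405432	-1.622222	-0.294815	-1.511605	-1.211358	-0.358025	-0.658272	-0.358025	-0.2	-0.784691	-0.800494	-1.574815	-0.768889	-0.705679
-0.355556	-0.37284	-0.224691	-0.224691	-0.380247	-0.301235	-0.232099	-0.422222	-0.214815	-0.404938	-0.358025	-0.224691	-0.271605	-0.224691	-0.2	-0.291358	-0.293827	-0.414815	-0.288889	-0.279012
-0.651111	-0.701235	-0.271605	-0.271605	-0.722716	-0.49358	-0.293086	-0.844444	-0.242963	-0.794321	-0.658272	-0.271605	-0.407654	-0.271605	-0.2	-0.464938	-0.472099	-0.822963	-0.457778	-0.429136
-0.355556	-0.37284	-0.224691	-0.224691	-0.380247	-0.301235	-0.232099	-0.422222	-0.214815	-0.404938	-0.358025	-0.224691	-0.271605	-0.224691	-0.2	-0.291358	-0.293827	-0.414815	-0.288889	-0.279012
-0.2	-0.2	-1	-1	-0.2	-0.2	0.2	-0.2	0.6	-0.2	-0.2	-0.2	-0.2	-0.2	0.6	-0.2	-0.2	-0.2	-0.2	-0.2
-0.775556	-0.839506	-0.291358	-0.291358	-0.866914	-0.574568	-0.318765	-1.022222	-0.254815	-0.958272	-0.784691	-0.291358	-0.464938	-0.291358	-0.2	-0.538025	-0.54716	-0.994815	-0.528889	-0.492346
-0.791111	-0.85679	-0.293827	-0.293827	-0.884938	-0.584691	-0.321975	-1.044444	-0.256296	-0.978765	-0.800494	-0.293827	-0.472099	-0.293827	-0.2	-0.54716	-0.556543	-1.016296	-0.537778	-0.500247
-1.553333	-1.703704	-0.414815	-0.414815	-1.768148	-1.080741	-0.479259	-2.133333	-0.328889	-1.982963	-1.574815	-0.414815	-0.822963	-0.414815	-0.2	-0.994815	-1.016296	-2.068889	-0.973333	-0.887407
-0.76	-0.822222	-0.288889	-0.288889	-0.848889	-0.564444	-0.315556	-1	-0.253333	-0.937778	-0.768889	-0.288889	-0.457778	-0.288889	-0.2	-0.528889	-0.537778	-0.973333	-0.52	-0.484444
-0.697778	-0.753086	-0.279012	-0.279012	-0.77679	-0.523951	-0.302716	-0.911111	-0.247407	-0.855802	-0.705679	-0.279012	-0.429136	-0.279012	-0.2	-0.492346	-0.500247	-0.887407	-0.484444	-0.45284
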