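code	formula	mono_mass	description
G	C2H3NO	57.02146	glycine
A	C3H5NO	71.03711	alanine
S	C3H5NO2	87.03203	serine
P	C5H7NO	97.05276	proline
V	C5H9NO	99.06841	valine
T	C4H7NO2	101.04768	threonine
C	C3H5NOS	103.00918	cysteine
L	C6H11NO	113.08406	leucine
I	C6H11NO	113.08406	isoleucine
Ile	C6H11NO	113.08406	isoleucine (explicit three-letter code)
N	C4H6N2O2	114.04293	asparagine
D	C4H5NO3	115.02694	aspartate
Q	C5H8N2O2	128.05858	glutamine
K	C6H12N2O	128.09496	lysine
E	C5H7NO3	129.04259	glutamate
M	C5H9NOS	131.04048	methionine
H	C6H7N3O	137.05891	histidine
F	C9H9NO	147.06841	phenylalanine
R	C6H12N4O	156.10111	arginine
Y	C9H9NO2	163.06333	tyrosine
W	C11H10N2O	186.07931	tryptophan
MeAla	C4H7NO	85.05276	N-methylalanine
Hty	C10H11NO2	177.07898	homotyrosine
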