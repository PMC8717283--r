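name	species	order	tas1r1	tas1r2	tas1r3	umami	sweet
Leishan spiny toad	Leptobrachium leishanense	Anura	1	1	0	no	no
Mexican spadefoot toad	Spea multiplicata	Anura	2	1	1	yes	yes
African bullfrog	Pyxicephalus adspersus	Anura	2	1	0	no	no
American bullfrog	Lithobates catesbeianus	Anura	2	0	0	no	no
Common frog	Rana temporaria	Anura	2(1PS)	2(1PS)	2	yes	yes
Tibetan Plateau frog	Nanorana parkeri	Anura	2	0	2(1PS)	yes	no
Eastern banjo frog	Limnodynastes dumerilii	Anura	1	1	1	yes	yes
Strawberry poison frog	Oophaga pumilio	Anura	1	1	0	no	no
Asiatic toad	Bufo gargarizans	Anura	1	1	0	no	no
African clawed frog	Xenopus laevis	Anura	0	0	0	no	no
Western clawed frog	Xenopus tropicalis	Anura	0	0	0	no	no
Two-lined caecilian	Rhinatrema bivittatum	Gymnophiona	1	1	1	yes	yes
Gaboon caecilian	Geotrypetes seraphini	Gymnophiona	1	0	1	yes	no
Tiny cayenne caecilian	Microcaecilia unicolor	Gymnophiona	1	1	2	yes	yes
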