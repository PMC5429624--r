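dot_bracket	rlc	note
.	l	single external
.....	lllll	all external
()	bb	empty hairpin
(...)	baaab	lone hairpin
(((...)))	bbbaaabbb	stacked hairpin
.((...)).	lbbaaabbl	external ends
((.((...))))	bbebbaaabbbb	5' bulge
((((...)).))	bbbbaaabbibb	3' bulge
((.((...)).))	bbdbbaaabbhbb	1-1 internal loop
((..((...))..))	bbddbbaaabbhhbb	2-2 internal loop
((...))((...))	bbaaabbbbaaabb	two exterior helices
.((...)).((...)).	lbbaaabblbbaaabbl	exterior spacers
((((...))((...))))	bccbaaabccbaaabccb	bare multiloop junction
((..((...))((...)).))	bcffcbaaabccbaaabckcb	multiloop, 2-run + 1-run
((.((...))((...))))	bcgcbaaabccbaaabccb	multiloop, single-nt left run
((((...))((...))..))	bccbaaabccbaaabcjjcb	multiloop, 2-nt final run
(.(...).(...).)	cgcaaacgcaaackc	three single-nt runs
(..(...)..(...)..)	cffcaaacffcaaacjjc	three 2-nt runs
..((((......))))..	llbbbbaaaaaabbbbll	long hairpin, external tails
((...((...))))	bbeeebbaaabbbb	3-nt 5' bulge
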