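# Fixture rewrite dictionary: surface<TAB>expansion<TAB>kind
# Entries are frequency-ranked (most frequent first); the synthetic noise
# injector uses this ranking as its Zipfian weight.
surface	expansion	kind
pt	patient	abbreviation
tr	trauma	abbreviation
fx	fracture	abbreviation
cont	contusion	abbreviation
lac	laceration	abbreviation
agg	aggression	abbreviation
sh	shoulder	abbreviation
eve	evening	abbreviation
morn	morning	abbreviation
aft	afternoon	abbreviation
yest	yesterday	abbreviation
wkp	workplace	abbreviation
w	with	abbreviation
rt	right	abbreviation
lt	left	abbreviation
hx	history	abbreviation
dx	diagnosis	abbreviation
rx	prescription	abbreviation
abd	abdomen	abbreviation
thx	thorax	abbreviation
vert	vertebral	abbreviation
med	medication	abbreviation
exam	examination	abbreviation
hosp	hospital	abbreviation
neuro	neurological	abbreviation
ortho	orthopedic	abbreviation
ped	pediatric	abbreviation
resp	respiratory	abbreviation
loc	loss of consciousness	acronym
gcs	glasgow coma scale	acronym
er	emergency room	acronym
bp	blood pressure	acronym
hr	heart rate	acronym
dv	domestic violence	acronym
ffx	facial fracture	acronym
paitent	patient	typo
patinet	patient	typo
fractrue	fracture	typo
fracure	fracture	typo
contusoin	contusion	typo
traum	trauma	typo
truama	trauma	typo
shoulde	shoulder	typo
shouldr	shoulder	typo
asault	assault	typo
assalt	assault	typo
hsuband	husband	typo
husbnd	husband	typo
lacertion	laceration	typo
aggresion	aggression	typo
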