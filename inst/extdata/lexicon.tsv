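# Fixture tagger lexicon: lemma<TAB>pos<TAB>supersenses
# Supersense groups are ';'-separated in decreasing sense-frequency order;
# ','-separated tags within a group are equally frequent (ties).
# Open-class (content) words only, as in WordNet; function words fall back
# to the NOUN/empty-supersense OOV path of the tagger.
lemma	pos	supersenses
# --- persons ---
husband	NOUN	noun.person
wife	NOUN	noun.person
neighbor	NOUN	noun.person
stranger	NOUN	noun.person
brother	NOUN	noun.person
colleague	NOUN	noun.person
patient	NOUN	noun.person
victim	NOUN	noun.person
father	NOUN	noun.person
# --- modes and instruments ---
punch	NOUN	noun.act
kick	NOUN	noun.act
aggression	NOUN	noun.act
assault	NOUN	noun.act
knife	NOUN	noun.artifact
stick	NOUN	noun.artifact
bottle	NOUN	noun.artifact
belt	NOUN	noun.artifact
club	NOUN	noun.artifact;noun.group
# --- time ---
evening	NOUN	noun.time
night	NOUN	noun.time
morning	NOUN	noun.time
afternoon	NOUN	noun.time
yesterday	NOUN	noun.time
today	NOUN	noun.time
# --- locations ---
home	NOUN	noun.location
workplace	NOUN	noun.location
street	NOUN	noun.location
school	NOUN	noun.location
park	NOUN	noun.location
bar	NOUN	noun.location,noun.artifact
hospital	NOUN	noun.location
# --- body parts ---
arm	NOUN	noun.body
head	NOUN	noun.body
shoulder	NOUN	noun.body
leg	NOUN	noun.body
face	NOUN	noun.body
wrist	NOUN	noun.body
chest	NOUN	noun.body
abdomen	NOUN	noun.body
thorax	NOUN	noun.body
# --- lesions and states ---
fracture	NOUN	noun.state
contusion	NOUN	noun.state
trauma	NOUN	noun.state
wound	NOUN	noun.state
bruise	NOUN	noun.state
laceration	NOUN	noun.state
injury	NOUN	noun.state
pain	NOUN	noun.feeling;noun.state
swollen	ADJECTIVE	adj.all
occipital	ADJECTIVE	adj.all
# --- other nouns ---
accident	NOUN	noun.event
cooking	NOUN	noun.act
sports	NOUN	noun.act
training	NOUN	noun.act
ladder	NOUN	noun.artifact
stairs	NOUN	noun.artifact
examination	NOUN	noun.act
diagnosis	NOUN	noun.cognition
history	NOUN	noun.cognition
medication	NOUN	noun.artifact
prescription	NOUN	noun.communication
# --- verbs ---
assaulted	VERB	verb.contact
attacked	VERB	verb.contact
beaten	VERB	verb.contact
punched	VERB	verb.contact
states	VERB	verb.communication
reports	VERB	verb.communication
denies	VERB	verb.communication
presents	VERB	verb.communication
suffered	VERB	verb.body
causing	VERB	verb.creation
fell	VERB	verb.motion
slipped	VERB	verb.motion
# --- adjectives / adverbs ---
accidental	ADJECTIVE	adj.all
right	ADJECTIVE	adj.all
left	ADJECTIVE	adj.all
blunt	ADJECTIVE	adj.all
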