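# Default violence-frame schema: per-field allowed PoS tags, allowed
# supersense tags, and prototype seed terms. Mirrors default_frame_schema().
similarity_threshold: 0.5
fields:
  AGENT:
    allowed_pos: [NOUN]
    allowed_sst: [noun.person]
    seed_terms: [husband, known_person]
  MODE_INSTRUMENT:
    allowed_pos: [NOUN]
    allowed_sst: [noun.object, noun.artifact, noun.state, noun.substance, noun.feeling, noun.act]
    seed_terms: [punch, knife]
  TIME:
    allowed_pos: [NOUN]
    allowed_sst: [noun.time]
    seed_terms: [evening, night]
  LOCATION:
    allowed_pos: [NOUN]
    allowed_sst: [noun.location]
    seed_terms: [home, workplace]
  BODY_PART:
    allowed_pos: [NOUN]
    allowed_sst: [noun.body]
    seed_terms: [arm, head]
  LESION_TYPE:
    allowed_pos: [NOUN, ADJECTIVE]
    allowed_sst: [noun.state, adj.all, noun.phenomenon]
    seed_terms: [fracture, contusion, trauma]
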