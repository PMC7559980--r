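# Common multiword locutions processed as single extended tokens
known person
loss of consciousness
bus station
emergency room
blood pressure
heart rate
domestic violence
facial fracture
glasgow coma scale
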