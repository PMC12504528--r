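Sentence 1: {sentence1}
Sentence 2: {sentence2}
How do you rate the memorability of Sentence 2 from 1 (not at all) to 10 (excellent)?
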