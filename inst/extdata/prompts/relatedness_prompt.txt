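Sentence 1: {sentence1}
Sentence 2: {sentence2}
How related are the two sentences from 1 (not at all) to 10 (highly)?
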