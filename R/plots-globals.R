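# .data is ggplot2's tidy-eval pronoun, resolved at plot time.
utils::globalVariables(".data")
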