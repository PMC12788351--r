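synthetic_evolved_individual.sexp

A SYNTHETIC illustrative GP individual written by hand in the package's
s-expression dialect (including the short operator aliases that rendered
evolved trees use: min3, max9, Compl, sqr, pDiv, if.then.else). It is shipped
so the parser and the sliding-window reconstructor have a realistic evolved-
looking input to exercise; it is NOT the output of any training run.
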