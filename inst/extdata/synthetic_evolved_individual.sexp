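(if.then.else (max9 (sqr Pixel13) (min3 Pixel7 Pixel12 Pixel13) (min3 Pixel13 Pixel14 Pixel19)
               (Compl Pixel1) (Compl Pixel25) (pDiv Pixel13 (Add Pixel7 0.75))
               (sqr (Compl Pixel18)) Pixel8 0.5)
  (Compl (min3 (Compl Pixel13) (pDiv Pixel12 (Add Pixel13 0.75)) (sqr (Compl Pixel14))))
  (Multiply 0.25 (sqr (max9 Pixel7 Pixel8 Pixel9 Pixel12 Pixel13 Pixel14 Pixel17 Pixel18 Pixel19))))
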