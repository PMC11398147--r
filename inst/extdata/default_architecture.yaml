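# Default sleep architecture: first-order Markov chain over the stages
# W (Wake), L (N1+N2), D (N3), R (REM) at 30-s epoch resolution.
# Rows are "from" stages in the order W, L, D, R and must sum to 1.
# The chain favors long N1+N2 runs, sustained N3 and REM periods, and
# brief awakenings; the night starts in Wake.
transition:
  W: [0.880, 0.100, 0.000, 0.020]
  L: [0.025, 0.885, 0.055, 0.035]
  D: [0.010, 0.070, 0.920, 0.000]
  R: [0.030, 0.050, 0.000, 0.920]
initial: [1.0, 0.0, 0.0, 0.0]
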