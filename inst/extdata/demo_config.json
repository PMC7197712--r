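{
  "n_genes": 400,
  "cells_scale": 0.05,
  "doublet_fraction": 0.05,
  "lowq_fraction": 0.025,
  "emission_mode": "poisson",
  "seed": 1
}
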