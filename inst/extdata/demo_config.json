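{
  "seed": 1,
  "simulate": {
    "reads": {
      "n_genes": 30,
      "n_cells": 25,
      "mean_molecules_per_cell": 60,
      "error_rate": 0.001,
      "snp_density": 0.001
    },
    "kinetics": {
      "n_genes": 40,
      "n_cells": 160
    },
    "clones": {
      "n_genes": 300,
      "n_normal_cells": 50,
      "clone_cells": 30,
      "shift": 0.8,
      "segment_frac": 0.2
    },
    "conditions": {
      "n_conditions": 3,
      "n_cells_per_condition": 120,
      "separation": 2,
      "dim": 3
    }
  },
  "moments": {
    "n_pcs": 20,
    "k": 20
  },
  "similarity": {
    "k": 20
  }
}
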