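{
  "note": "SYNTHETIC archetype parameterization (small/medium forage fish + large piscivore). These are NOT fitted Baltic stock parameters; see the methods vignette.",
  "species": [
    {
      "name": "sprat",
      "w0": 0.001,
      "Wi": 25,
      "wmat": 7,
      "m": 5,
      "n": 0.75,
      "p": 0.75,
      "q": 0.8,
      "h": 18,
      "ks": 2.16,
      "alpha": 0.6,
      "f0": 0.6,
      "beta": 30000,
      "sigma": 2,
      "mu0": 0.6,
      "xi": 0.1,
      "erepro": 0.01,
      "Rmax": 300000000000,
      "F": 0.3
    },
    {
      "name": "herring",
      "w0": 0.001,
      "Wi": 250,
      "wmat": 40,
      "m": 5,
      "n": 0.75,
      "p": 0.75,
      "q": 0.8,
      "h": 15,
      "ks": 1.8,
      "alpha": 0.6,
      "f0": 0.6,
      "beta": 30000,
      "sigma": 2,
      "mu0": 0.6,
      "xi": 0.1,
      "erepro": 0.01,
      "Rmax": 30000000000,
      "F": 0.25
    },
    {
      "name": "cod",
      "w0": 0.001,
      "Wi": 20000,
      "wmat": 1000,
      "m": 5,
      "n": 0.75,
      "p": 0.75,
      "q": 0.8,
      "h": 25,
      "ks": 3,
      "alpha": 0.6,
      "f0": 0.6,
      "beta": 300,
      "sigma": 1.5,
      "mu0": 0.6,
      "xi": 0.1,
      "erepro": 0.001,
      "Rmax": 100000000,
      "F": 0.7
    }
  ],
  "resources": [
    {
      "name": "pelagic",
      "r0": 4,
      "kappa": 100000000000,
      "lambda": 2.05,
      "w_min": 1e-07,
      "w_max": 0.1,
      "p": 0.75
    },
    {
      "name": "benthic",
      "r0": 4,
      "kappa": 5000000000,
      "lambda": 2.05,
      "w_min": 1e-05,
      "w_max": 20,
      "p": 0.75
    }
  ],
  "theta_R": [
    [1, 0],
    [0.7, 0.3],
    [0.3, 1]
  ],
  "thermal": {
    "Tref": 283.15,
    "k_B": 8.617e-05,
    "scenario": "none",
    "E_met": [0.59, 0.08],
    "E_cons": [0.69, 0.1],
    "E_search": [0.69, 0.1],
    "E_mort": [0.59, 0.08],
    "E_r0": [0.63, 0.1],
    "E_kappa": [0.63, 0.1]
  },
  "no_w": 100,
  "solver": {
    "dt": 0.1,
    "t_max": 200,
    "steady_tol": 0.0001,
    "steady_window": 10
  }
}
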