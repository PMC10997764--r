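{
  "null": {},
  "wounding": {
    "wave_speed": 0.19,
    "sa_onset": null,
    "kinetics": {
      "k": 0.012619424817741,
      "kd": 0.171053900482891,
      "kf1": 0,
      "kf_chain": [0, 0],
      "ks": 0,
      "ki": 0,
      "kr": 0,
      "n_intermediates": 3,
      "a0": 0.0637787576026727,
      "p0": 38.964435913219,
      "pf0": 0,
      "pi0": 0
    }
  },
  "xcc": {
    "wave_speed": 0.2,
    "sa_onset": 87.0406504065041,
    "sa_diffusion": 0.01,
    "sa_sigma0": 0.25,
    "sa_amp": 20.548299053437,
    "kinetics": {
      "k": 0.00447288342621142,
      "kd": 0.117621052228317,
      "kf1": 0.0001,
      "kf_chain": [0.1, 0.1],
      "ks": 0.1,
      "ki": 0.0002,
      "kr": 0.05,
      "n_intermediates": 3,
      "a0": 0.156496012676822,
      "p0": 62.8752116207178,
      "pf0": 150,
      "pi0": 5
    }
  },
  "light": {
    "wave_speed": 0.08,
    "sa_onset": 20.4945945945946,
    "sa_diffusion": 0.01,
    "sa_sigma0": 0.25,
    "sa_amp": 24.5357600321739,
    "kinetics": {
      "k": 0.00426716569376555,
      "kd": 0.127640424489327,
      "kf1": 0.0001,
      "kf_chain": [0.5, 0.5],
      "ks": 0.5,
      "ki": 0.0002,
      "kr": 0.05,
      "n_intermediates": 3,
      "a0": 1.28290822199375,
      "p0": 65.1151005537525,
      "pf0": 150,
      "pi0": 5,
      "t2": 130,
      "p2": 32
    }
  },
  "heat": {
    "wave_speed": 1.2,
    "sa_onset": 33.6428571428571,
    "sa_diffusion": 0.01,
    "sa_sigma0": 0.25,
    "sa_amp": 15.9442506074256,
    "kinetics": {
      "k": 0.0202097008243094,
      "kd": 0.016922284398463,
      "kf1": 0.0001,
      "kf_chain": [0.15, 0.15],
      "ks": 0.15,
      "ki": 0.0002,
      "kr": 0.05,
      "n_intermediates": 3,
      "a0": 0.0298161483489932,
      "p0": 24.4773166866708,
      "pf0": 150,
      "pi0": 5,
      "t2": 100,
      "p2": 6
    }
  }
}
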