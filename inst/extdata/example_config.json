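{
  "seed": 20,
  "cells": [
    {"construct": 2, "scenario": 0, "method": "t_test", "delta": 1.85,
     "n": 280, "n_sim": 50},
    {"construct": 2, "scenario": 1, "method": "t_test", "delta": 1.85,
     "n": 280, "n_sim": 50}
  ],
  "curves": false
}
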