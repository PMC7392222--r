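{
  "preset": "two-element",
  "populations": 100,
  "cells": 50,
  "seed": 7,
  "p": 0.85,
  "lambda": 5,
  "phases": 11
}
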