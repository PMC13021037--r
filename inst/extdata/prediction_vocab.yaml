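# Native call vocabulary of each in-silico tool mapped to the common
# damaging / tolerated dichotomy used by the consensus engine.
SIFT:
  deleterious: damaging
  deleterious_low_confidence: damaging
  damaging: damaging
  tolerated: tolerated
  tolerated_low_confidence: tolerated
PolyPhen:
  probably_damaging: damaging
  possibly_damaging: damaging
  benign: tolerated
FATHMM:
  D: damaging
  T: tolerated
MutationTaster:
  A: damaging
  D: damaging
  "N": tolerated
  P: tolerated
MutationAssessor:
  H: damaging
  M: damaging
  L: tolerated
  "N": tolerated
PROVEAN:
  D: damaging
  "N": tolerated
SIFT-indel:
  damaging: damaging
  neutral: tolerated
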