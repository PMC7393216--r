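# Default marker-gene rules for metabolic potential calls.
# Each entry is a boolean expression over marker symbols (see
# sodamag::marker_vocabulary); edit or extend and load with load_ruleset().
cbb_carbon_fixation: "prk & rbcL & rbcS"
wood_ljungdahl_carbon_fixation: "cooS & acsB & cdhD & cdhE"
sulfide_oxidation: "sqr | fccB"
sulfite_oxidation: "soeA & soeB & soeC"
thiosulfate_oxidation_sox: "soxB & soxY & soxZ"
thiosulfate_oxidation_doxD: "doxD"
polysulfide_thiosulfate_respiration: "psrA_phsA"
tetrathionate_respiration: "ttrA & ttrB"
nitrogen_fixation: "nifH & nifD & nifK"
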