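# Placeholder list of commonly shared nonserious adverse events filtered
# before ranking top per-group events. This is a small default, not a
# curated list: replace it with a study-specific file for real analyses.
headache
fatigue
nausea
dizziness
nasopharyngitis
diarrhoea
vomiting
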