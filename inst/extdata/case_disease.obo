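format-version: 1.2
ontology: synthetic-disease-subset

[Term]
id: DOID:4
name: disease

[Term]
id: DOID:1579
name: respiratory system disease
is_a: DOID:4 ! disease

[Term]
id: DOID:6051
name: bronchitis
is_a: DOID:1579 ! respiratory system disease

[Term]
id: DOID:6132
name: chronic bronchitis
is_a: DOID:6051 ! bronchitis

[Term]
id: DOID:17
name: musculoskeletal system disease
is_a: DOID:4 ! disease

[Term]
id: DOID:848
name: arthritis
is_a: DOID:17 ! musculoskeletal system disease

[Term]
id: DOID:7148
name: rheumatoid arthritis
is_a: DOID:848 ! arthritis

[Term]
id: DOID:850
name: lung disease
is_a: DOID:1579 ! respiratory system disease
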