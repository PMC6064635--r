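PMID- 10000001
TI  - Dietary fibre in irritable bowel syndrome
AB  - Dietary fibre intake was assessed in patients; fibre and lactose were
      compared with placebo.
DP  - 2001

PMID- 10000002
TI  - Gliadin and wheat proteins in coeliac disease
AB  - Wheat gliadin and gluten fractions were measured; rye and barley were
      included as controls.
DP  - 1995

PMID- 10000003
TI  - Vitamin D status in inflammatory bowel disease
AB  - Vitamin D and cholecalciferol levels were measured; obesity and growth
      were recorded.
DP  - 2012

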