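term_id	namespace_code	canonical_name	synonyms
NUTR:0001	-1	wheat	triticum
NUTR:0002	-1	gliadin	
NUTR:0003	-1	gluten	
NUTR:0004	-1	rye	secale
NUTR:0005	-1	barley	hordeum
NUTR:0006	-1	oats	oat
NUTR:0007	-1	fibre	fiber|dietary fibre|dietary fiber
NUTR:0008	-1	lactose	milk sugar
NUTR:0009	-1	butyrate	butyric acid
NUTR:0010	-1	short-chain fatty acids	scfa|scfas|short chain fatty acids
NUTR:0011	-1	fatty acids	
NUTR:0012	-1	omega-3 fatty acids	omega-3|n-3 fatty acids
NUTR:0013	-1	n-6 fatty acids	omega-6 fatty acids|omega-6
NUTR:0014	-1	vitamin d	cholecalciferol|calciferol
NUTR:0015	-1	vitamin b12	cobalamin
NUTR:0016	-1	folate	folic acid
NUTR:0017	-1	iron	
NUTR:0018	-1	zinc	
NUTR:0019	-1	calcium	
NUTR:0020	-1	curcumin	turmeric extract
NUTR:0021	-1	glucose	dextrose
NUTR:0022	-1	fructose	
NUTR:0023	-1	sucrose	table sugar
NUTR:0024	-1	starch	
NUTR:0025	-1	casein	
NUTR:0026	-1	whey	
NUTR:0027	-1	polyphenols	polyphenol
NUTR:0028	-1	probiotics	probiotic
NUTR:0029	-1	prebiotics	prebiotic
NUTR:0030	-1	fodmap	fodmaps
PHEN:0001	-26	obesity	obese
PHEN:0002	-26	growth	growth retardation
PHEN:0003	-26	malnutrition	undernutrition
PHEN:0004	-26	wheat allergy	
PHEN:0005	-26	anaemia	anemia
PHEN:0006	-26	diarrhoea	diarrhea
PROC:0001	-21	fermentation	
PROC:0002	-21	inflammation	inflammatory response
ORG:0001	-2	bifidobacterium	bifidobacteria
ORG:0002	-2	lactobacillus	lactobacilli
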