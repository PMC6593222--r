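"""Freeze reference Porter stems for a ~1000-word vocabulary into
tests/testthat/fixtures/porter-reference.tsv (word TAB stem)."""

import sys, os

sys.path.insert(0, os.path.dirname(__file__))
from porter_oracle import PorterStemmer

classic = """caresses ponies ties caress cats feed agreed plastered bled
motoring sing conflated troubled sized hopping tanned falling hissing fizzed
failing filing happy sky relational conditional rational valenci hesitanci
digitizer operator feudalism decisiveness hopefulness callousness formaliti
sensitiviti sensibiliti triplicate formative formalize electriciti electrical
hopeful goodness revival allowance inference airliner gyroscopic adjustable
defensible irritant replacement adjustment dependent adoption communism
activate angulariti homologous effective bowdlerize probate rate cease
controll roll generalization generalizations oscillators""".split()

domain = """antibiotics antibiotic saline nonsaline soil soils sediment
sediments microbial microbiome microbiomes bacteria bacterial archaea fungal
fungi community communities diversity abundance abundances sample samples
sampling sampled sequence sequences sequencing sequenced amplicon amplicons
fermentation fermented environmental environments ecology ecological
gradient gradients acidity alkaline alkalinity nutrient nutrients nitrogen
carbon phosphorus grassland grasslands forest forests agricultural
agriculture cultivation cultivated temperate tropical arid desert wetland
wetlands marine freshwater estuary estuaries rhizosphere roots leaves
compost composted manure fertilizer fertilized fertilization irrigation
irrigated drought drainage elevation latitude longitude temperature
moisture humidity salinity conductivity texture clay loam sandy silt
treatment treatments treated untreated control controls controlled
replicate replicates replication replicated subject subjects patient
patients infant infants adult adults feces fecal stool gut intestinal oral
skin nasal vaginal mucosal saliva plaque dental host hosts disease diseases
diseased healthy health obesity obese diabetes diabetic inflammation
inflammatory infection infections infected medication medications dosage
probiotics prebiotics dietary diet diets vegetarian omnivore herbivore
carnivore captivity captive wild domesticated bovine porcine murine avian
plant plants vegetation biomass litter decomposition decomposed respiration
photosynthesis methane methanogenesis sulfate sulfur oxidation reduction
anaerobic aerobic hypoxic oxygen depth depths surface subsurface core cores
horizon horizons topsoil mineral minerals organic inorganic matter
extraction extracted amplification amplified polymerase primers barcode
barcodes multiplexed denoising clustering clustered taxonomy taxonomic
taxon taxa genus genera species phylum phyla family families order class
kingdom domain lineage lineages annotation annotated classifier classified
classification alignment aligned phylogeny phylogenetic ordination
rarefaction rarefied normalization normalized filtering filtered quality
chimeric chimeras singleton singletons prevalence prevalent occurrence
occurrences observation observations metadata variable variables description
descriptions category categories identifier identifiers partition partitions
partitioned context contexts protocol protocols preparation preparations
processing processed pipeline pipelines workflow workflows repository
deposited retrieval retrieved discovery indexing indexed queries searching
searched matching matched intersection union difference membership stems
stemming stemmed tokens tokenized vocabulary""".split()

bases = """walk jump test index load store fetch link merge filter scan
parse split trim drop keep mark label group count order rank score weight
shift clean check prove serve note time name form part land hand help work
play move turn call mail ship pack open close start stop run read write
code plan farm mine mix map fit dig plot till seed crop feed heat cool dry
wet wash soak""".split()

suffixes = ["", "s", "ed", "ing", "er", "ers", "ation", "ations", "able",
            "ness", "ful", "less", "ment", "ments", "ally", "ization"]

vocab = []
seen = set()
for w in classic + domain:
    w = w.lower()
    if w not in seen:
        seen.add(w)
        vocab.append(w)
for b in bases:
    for suf in suffixes:
        w = b + suf
        if w not in seen:
            seen.add(w)
            vocab.append(w)
        if len(vocab) >= 1000:
            break
    if len(vocab) >= 1000:
        break

p = PorterStemmer()
out = os.path.join(os.path.dirname(__file__), "..", "tests", "testthat",
                   "fixtures", "porter-reference.tsv")
os.makedirs(os.path.dirname(out), exist_ok=True)
with open(out, "w") as fh:
    fh.write("word\tstem\n")
    for w in vocab:
        fh.write(f"{w}\t{p.stem(w)}\n")
print(f"wrote {len(vocab)} pairs to {out}")
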