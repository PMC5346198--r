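# Repository endpoint templates (KEY=value). Placeholders in braces are
# substituted by the URL interfaces. The Entrez base is the classic http
# form; repoint it at the https mirror here if your deployment needs it.
ENTREZ=http://eutils.ncbi.nlm.nih.gov/entrez/eutils
MALA_CARDS=https://www.malacards.org/search/results/{term}
BIOMODELS=https://www.ebi.ac.uk/biomodels/model/download/{id}
BIOMODELS_SEARCH=https://www.ebi.ac.uk/biomodels/search?query={term}
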