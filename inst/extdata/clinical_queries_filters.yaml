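# PubMed Clinical Queries therapy filters (2005 revision, as shipped in
# PubMed's Clinical Queries page) and limit expansions.  Filter wording
# drifts over time; edit this file or pass a modified copy to
# filter_config() to pin a different vintage.
therapy_narrow: >-
  randomized controlled trial[Publication Type] OR (randomized[Title/Abstract]
  AND controlled[Title/Abstract] AND trial[Title/Abstract])
therapy_broad: >-
  (clinical[Title/Abstract] AND trial[Title/Abstract]) OR clinical trials as
  topic[MeSH Terms] OR clinical trial[Publication Type] OR
  random*[Title/Abstract] OR random allocation[MeSH Terms] OR therapeutic
  use[MeSH Subheading]
english: English[lang]
human: humans[MeSH Terms]
aim: jsubsetaim
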