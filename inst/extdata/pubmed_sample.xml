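<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>90000001</PMID>
      <Article>
        <ArticleTitle>Effect of ketoconazole on midazolam pharmacokinetics.</ArticleTitle>
        <Abstract>
          <AbstractText>Ketoconazole significantly increased the AUC of midazolam by 3.2 fold (P&lt;0.01). The Cmax of midazolam rose 2.1 fold. No serious adverse events were observed.</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>90000002</PMID>
      <Article>
        <ArticleTitle>A record without an abstract.</ArticleTitle>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
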