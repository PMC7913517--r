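<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID Version="1">10000001</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2019</Year></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>Transcriptome profiling of lesional psoriasis skin.</ArticleTitle>
        <Abstract>
          <AbstractText Label="BACKGROUND">Psoriasis is a chronic inflammatory skin disease.</AbstractText>
          <AbstractText Label="RESULTS">RNA-seq revealed IL17A driven expression programs.</AbstractText>
        </Abstract>
      </Article>
      <MeshHeadingList>
        <MeshHeading><DescriptorName>Psoriasis</DescriptorName></MeshHeading>
        <MeshHeading><DescriptorName>Transcriptome</DescriptorName></MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID Version="1">10000002</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><MedlineDate>2018 Jan-Feb</MedlineDate></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>Skin microbiome shifts in atopic dermatitis.</ArticleTitle>
        <Abstract>
          <AbstractText>16S sequencing showed reduced microbial diversity in lesional skin.</AbstractText>
        </Abstract>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID Version="1">10000003</PMID>
      <Article>
        <Journal>
          <JournalIssue>
            <PubDate><Year>2020</Year></PubDate>
          </JournalIssue>
        </Journal>
        <ArticleTitle>Comment on hidradenitis suppurativa therapy.</ArticleTitle>
      </Article>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
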