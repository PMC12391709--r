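# Drug dictionary: normalized generic name -> drug class.
# Lookup is case- and whitespace-insensitive after normalization;
# names absent from every class resolve to "other".
classes:
  pah_target:
    - sildenafil
    - tadalafil
    - ambrisentan
    - macitentan
    - riociguat
    - selexipag
    - beraprost
    - treprostinil
  vasopressor:
    - norepinephrine
    - dobutamine
    - mesalamine
    - ephedrine
    - dopamine
    - phenylephrine
  antiemetic:
    - metoclopramide
    - tropisetron
    - dolasetron
    - palonosetron
    - ondansetron
    - fosaprepitant
    - aprepitant
    - phenformin
  antidiarrheal:
    - montmorillonite powder
    - bifidobacterium bifidum tetragonum
    - live combined bifidobacterium and lactobacillus tablets
    - bifidobacterium live bacteria
    - loperamide
    - saccharomyces boulardii
    - live bacillus cereus bifidus
  hepatoprotective:
    - glutathione
    - diammonium glycyrrhizinate
    - magnesium isoglycyrrhizinate
    - compound glycyrrhizin
    - monoammonium cysteine glycyrrhizinate
    - polyene phosphatidylcholine
    - ursodeoxycholic acid
    - silymarin
  laxative:
    - glycerine enema
    - lactulose
    - lactulose oral solution
    - hemp nut soft gels
    - bisacodyl
    - bisacodyl enteric tablets
    - senna
  antihistamine:
    - loratadine
    - ebastine
    - chlorpheniramine maleate
    - chlorpheniramine
    - olopatadine
    - cetirizine
    - cyproheptadine
    - promethazine
    - diphenhydramine
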