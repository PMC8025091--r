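# Keyword vocabulary for Portuguese ingredient-list scanning.
#
# Terms are matched against NORMALIZED text: lowercase, accents stripped
# (ç→c, ã→a, ...), punctuation replaced by single spaces, whitespace
# collapsed. Store terms already normalized. Matching is whole-token:
# "sal" matches the token "sal" but not "salsa". A trailing "*" on a
# token makes it a prefix stem ("xarope*" matches "xarope", "xaropes").
# Multi-word terms are matched as consecutive token sequences.
#
# Negation phrases ("sem adicao de acucar") are NOT applied by default;
# the per-set `negations` lists ship empty and exist as a hook.
added_sugar:
  terms:
    - acucar*
    - mel
    - melaco
    - xarope*
    - maltodextrina
    - glicose
    - glucose
    - frutose
    - suco concentrado
    - chocolate*
    - doce de leite
  negations: []
added_salt:
  terms:
    - sal
    - cloreto de sodio
    - queijo*
    - embutido*
  negations: []
added_fat:
  terms:
    - oleo*
    - azeite*
    - azeitona*
    - manteiga
    - banha
    - creme de leite
    - gordura vegetal
    - gordura animal
  negations: []
nns:
  terms:
    - aspartame
    - sacarina
    - sucralose
    - ciclamato
    - acessulfame*
    - acesulfame*
    - estevia
    - stevia
    - polidextrose
    - maltitol
    - manitol
    - isomalt*
    - neotame
    - xilitol
    - taumatina
    - advantame
  negations: []
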