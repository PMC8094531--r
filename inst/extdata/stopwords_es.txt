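# Spanish stopword list (function words: articles, prepositions,
# conjunctions, pronouns, common auxiliary/copular verb forms, adverbs).
# One entry per line; matching is case-insensitive.
de
la
que
el
en
y
a
los
del
se
las
por
un
para
con
no
una
su
al
lo
como
más
pero
sus
le
ya
o
este
sí
porque
esta
entre
cuando
muy
sin
sobre
también
me
hasta
hay
donde
quien
desde
todo
nos
durante
todos
uno
les
ni
contra
otros
ese
eso
ante
ellos
e
esto
mí
antes
algunos
qué
unos
yo
otro
otras
otra
él
tanto
esa
estos
mucho
quienes
nada
muchos
cual
poco
ella
estar
estas
algunas
algo
nosotros
mi
mis
tú
te
ti
tu
tus
ellas
nosotras
vosotros
vosotras
os
mío
mía
míos
mías
tuyo
tuya
tuyos
tuyas
suyo
suya
suyos
suyas
nuestro
nuestra
nuestros
nuestras
vuestro
vuestra
vuestros
vuestras
esos
esas
estoy
estás
está
estamos
estáis
están
esté
estés
estemos
estéis
estén
estaré
estarás
estará
estaremos
estaréis
estarán
estaría
estarías
estaríamos
estaríais
estarían
estaba
estabas
estábamos
estabais
estaban
estuve
estuviste
estuvo
estuvimos
estuvisteis
estuvieron
estando
estado
estada
estados
estadas
estad
he
has
ha
hemos
habéis
han
haya
hayas
hayamos
hayáis
hayan
habré
habrás
habrá
habremos
habréis
habrán
había
habías
habíamos
habíais
habían
habido
habiendo
soy
eres
es
somos
sois
son
sea
seas
seamos
seáis
sean
seré
serás
será
seremos
seréis
serán
sería
serías
seríamos
seríais
serían
era
eras
éramos
erais
eran
fui
fuiste
fue
fuimos
fuisteis
fueron
fuera
fueras
fuéramos
fuerais
fueran
siendo
sido
ser
tengo
tienes
tiene
tenemos
tenéis
tienen
tenga
tengas
tengamos
tengan
tendré
tendrá
tendremos
tendrán
tenía
tenías
teníamos
tenían
tuve
tuvo
tuvimos
tuvieron
teniendo
tenido
tener
hacer
hace
hacen
hizo
hecho
puede
pueden
podría
podrían
debe
deben
cada
según
además
así
aunque
bien
mal
sólo
solo
tras
pues
luego
aún
mientras
dentro
fuera
cerca
lejos
aquí
allí
ahí
ahora
entonces
después
siempre
nunca
tampoco
casi
menos
demasiado
bastante
tal
tales
cualquier
cualquiera
varios
varias
ambos
ambas
etc
mediante
respecto
través
vez
veces
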