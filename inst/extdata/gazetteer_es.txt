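# Geographic gazetteer: countries, regions/cities and nationality
# adjectives in Spanish. One entry per line (multi-word entries are
# matched on contiguous token spans); matching is case-insensitive.
españa
méxico
méjico
argentina
colombia
chile
perú
venezuela
ecuador
bolivia
paraguay
uruguay
cuba
guatemala
honduras
nicaragua
panamá
brasil
portugal
francia
italia
alemania
suiza
austria
bélgica
holanda
inglaterra
irlanda
escocia
grecia
rusia
china
japón
india
canadá
marruecos
egipto
turquía
israel
australia
estados unidos
reino unido
puerto rico
costa rica
el salvador
república dominicana
países bajos
nueva york
nueva zelanda
américa latina
europa
américa
asia
áfrica
oceanía
latinoamérica
iberoamérica
sudamérica
centroamérica
norteamérica
madrid
barcelona
valencia
sevilla
zaragoza
bilbao
granada
salamanca
andalucía
cataluña
galicia
asturias
cantabria
extremadura
navarra
aragón
castilla
país vasco
buenos aires
bogotá
lima
santiago
caracas
quito
montevideo
asunción
habana
español
española
españoles
españolas
mexicano
mexicana
mexicanos
mexicanas
argentino
argentina
argentinos
argentinas
colombiano
colombiana
colombianos
colombianas
chileno
chilena
chilenos
chilenas
peruano
peruana
peruanos
peruanas
venezolano
venezolana
venezolanos
venezolanas
ecuatoriano
ecuatoriana
boliviano
boliviana
paraguayo
paraguaya
uruguayo
uruguaya
cubano
cubana
cubanos
cubanas
guatemalteco
guatemalteca
hondureño
hondureña
nicaragüense
panameño
panameña
dominicano
dominicana
brasileño
brasileña
portugués
portuguesa
francés
francesa
franceses
italiano
italiana
italianos
alemán
alemana
alemanes
suizo
suiza
austriaco
belga
holandés
holandesa
inglés
inglesa
ingleses
irlandés
escocés
griego
griega
ruso
rusa
chino
china
japonés
japonesa
indio
india
canadiense
marroquí
egipcio
turco
israelí
australiano
estadounidense
norteamericano
norteamericana
británico
británica
europeo
europea
europeos
europeas
americano
americana
americanos
americanas
latinoamericano
latinoamericana
iberoamericano
iberoamericana
sudamericano
sudamericana
hispano
hispana
hispanoamericano
hispanoamericana
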