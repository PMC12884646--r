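# Built-in lexical taxonomy: a WordNet-style hypernym forest covering the
# behavioural-symptom vocabulary the package operates on. Nodes are sense
# identifiers ("task.n"); a word can map to several senses. Path similarity
# between two senses in the same tree is 1 / (1 + shortest path length
# through the hypernym hierarchy); words sharing a sense (synonyms) score 1.

TAXO_PARENT <- c(
  # noun hierarchy
  "physical_entity.n" = "entity.n",
  "abstraction.n"     = "entity.n",
  "object.n"          = "physical_entity.n",
  "artifact.n"        = "object.n",
  "seat.n"            = "artifact.n",
  "motor.n"           = "artifact.n",
  "toy.n"             = "artifact.n",
  "tool.n"            = "artifact.n",
  "furniture.n"       = "artifact.n",
  "chair.n"           = "furniture.n",
  "table.n"           = "furniture.n",
  "book.n"            = "artifact.n",
  "clothes.n"         = "artifact.n",
  "thing.n"           = "object.n",
  "body_part.n"       = "object.n",
  "hand.n"            = "body_part.n",
  "foot.n"            = "body_part.n",
  "face.n"            = "body_part.n",
  "tooth.n"           = "body_part.n",
  "hair.n"            = "body_part.n",
  "organism.n"        = "physical_entity.n",
  "person.n"          = "organism.n",
  "child.n"           = "person.n",
  "parent.n"          = "person.n",
  "teacher.n"         = "person.n",
  "friend.n"          = "person.n",
  "food.n"            = "object.n",
  "location.n"        = "physical_entity.n",
  "room.n"            = "location.n",
  "classroom.n"       = "room.n",
  "school.n"          = "location.n",
  "home.n"            = "location.n",
  "house.n"           = "location.n",
  "psych_feature.n"   = "abstraction.n",
  "cognition.n"       = "psych_feature.n",
  "attention.n"       = "cognition.n",
  "memory.n"          = "cognition.n",
  "interest.n"        = "cognition.n",
  "feeling.n"         = "psych_feature.n",
  "sadness.n"         = "feeling.n",
  "anger.n"           = "feeling.n",
  "fear.n"            = "feeling.n",
  "worry.n"           = "feeling.n",
  "mood.n"            = "feeling.n",
  "motivation.n"      = "psych_feature.n",
  "effort.n"          = "motivation.n",
  "energy.n"          = "motivation.n",
  "attribute.n"       = "abstraction.n",
  "quality.n"         = "attribute.n",
  "difficulty.n"      = "quality.n",
  "state.n"           = "attribute.n",
  "situation.n"       = "state.n",
  "behavior.n"        = "attribute.n",
  "symptom.n"         = "state.n",
  "appetite.n"        = "state.n",
  "communication.n"   = "abstraction.n",
  "question.n"        = "communication.n",
  "answer.n"          = "communication.n",
  "instruction.n"     = "communication.n",
  "rule.n"            = "communication.n",
  "conversation.n"    = "communication.n",
  "story.n"           = "communication.n",
  "detail.n"          = "communication.n",
  "picture.n"         = "communication.n",
  "event.n"           = "abstraction.n",
  "act.n"             = "event.n",
  "activity.n"        = "act.n",
  "task.n"            = "activity.n",
  "work.n"            = "activity.n",
  "homework.n"        = "work.n",
  "play.n"            = "activity.n",
  "game.n"            = "play.n",
  "leisure.n"         = "play.n",
  "mistake.n"         = "act.n",
  "turn.n"            = "act.n",
  "tantrum.n"         = "act.n",
  "happening.n"       = "event.n",
  "time_period.n"     = "abstraction.n",
  "day.n"             = "time_period.n",
  "night.n"           = "time_period.n",
  "morning.n"         = "time_period.n",
  "bedtime.n"         = "time_period.n",
  "sleep.n"           = "state.n",
  "meal.n"            = "event.n",
  # verb hierarchy
  "move.v"            = "act.v",
  "run.v"             = "move.v",
  "climb.v"           = "move.v",
  "walk.v"            = "move.v",
  "jump.v"            = "move.v",
  "leave.v"           = "move.v",
  "go.v"              = "move.v",
  "come.v"            = "move.v",
  "drive.v"           = "move.v",
  "fidget.v"          = "move.v",
  "squirm.v"          = "fidget.v",
  "wiggle.v"          = "fidget.v",
  "tap.v"             = "move.v",
  "sit.v"             = "move.v",
  "stand.v"           = "move.v",
  "throw.v"           = "move.v",
  "communicate.v"     = "act.v",
  "talk.v"            = "communicate.v",
  "say.v"             = "communicate.v",
  "tell.v"            = "communicate.v",
  "ask.v"             = "communicate.v",
  "answer.v"          = "communicate.v",
  "blurt.v"           = "communicate.v",
  "interrupt.v"       = "communicate.v",
  "intrude.v"         = "interrupt.v",
  "shout.v"           = "talk.v",
  "scream.v"          = "shout.v",
  "argue.v"           = "communicate.v",
  "perceive.v"        = "act.v",
  "listen.v"          = "perceive.v",
  "hear.v"            = "perceive.v",
  "see.v"             = "perceive.v",
  "watch.v"           = "see.v",
  "notice.v"          = "perceive.v",
  "think.v"           = "act.v",
  "organize.v"        = "think.v",
  "plan.v"            = "think.v",
  "arrange.v"         = "organize.v",
  "concentrate.v"     = "think.v",
  "attend.v"          = "concentrate.v",
  "focus.v"           = "concentrate.v",
  "remember.v"        = "think.v",
  "forget.v"          = "think.v",
  "worry.v"           = "think.v",
  "possession.v"      = "act.v",
  "lose.v"            = "possession.v",
  "misplace.v"        = "lose.v",
  "give.v"            = "possession.v",
  "take.v"            = "possession.v",
  "get.v"             = "possession.v",
  "steal.v"           = "take.v",
  "share.v"           = "give.v",
  "make.v"            = "act.v",
  "create.v"          = "make.v",
  "build.v"           = "make.v",
  "draw.v"            = "make.v",
  "write.v"           = "make.v",
  "continue.v"        = "act.v",
  "sustain.v"         = "continue.v",
  "maintain.v"        = "sustain.v",
  "keep.v"            = "continue.v",
  "remain.v"          = "continue.v",
  "stay.v"            = "remain.v",
  "wait.v"            = "continue.v",
  "fail.v"            = "act.v",
  "neglect.v"         = "fail.v",
  "avoid.v"           = "act.v",
  "refuse.v"          = "avoid.v",
  "ignore.v"          = "avoid.v",
  "finish.v"          = "act.v",
  "complete.v"        = "finish.v",
  "end.v"             = "finish.v",
  "stop.v"            = "finish.v",
  "start.v"           = "act.v",
  "engage.v"          = "act.v",
  "participate.v"     = "engage.v",
  "play.v"            = "engage.v",
  "require.v"         = "act.v",
  "need.v"            = "require.v",
  "want.v"            = "require.v",
  "expect.v"          = "think.v",
  "anticipate.v"      = "expect.v",
  "distract.v"        = "act.v",
  "disturb.v"         = "distract.v",
  "bother.v"          = "disturb.v",
  "annoy.v"           = "disturb.v",
  "seem.v"            = "be.v",
  "appear.v"          = "seem.v",
  "follow.v"          = "act.v",
  "obey.v"            = "follow.v",
  "help.v"            = "act.v",
  "try.v"             = "act.v",
  "feel.v"            = "perceive.v",
  "sleep.v"           = "act.v",
  "nap.v"             = "sleep.v",
  "wake.v"            = "act.v",
  "eat.v"             = "act.v",
  "fight.v"           = "act.v",
  "hit.v"             = "fight.v",
  "cry.v"             = "act.v",
  "whine.v"           = "cry.v",
  "sulk.v"            = "act.v",
  "defy.v"            = "act.v",
  "destroy.v"         = "act.v",
  "blame.v"           = "communicate.v",
  "read.v"            = "perceive.v",
  "wash.v"            = "act.v",
  "brush.v"           = "act.v",
  "dress.v"           = "act.v",
  "tidy.v"            = "organize.v",
  "have.v"            = "act.v",
  "do.v"              = "act.v",
  # adjective clusters (shallow trees per attribute family)
  "careless.a"        = "attentive_attr.a",
  "careful.a"         = "attentive_attr.a",
  "forgetful.a"       = "attentive_attr.a",
  "close.a"           = "nearness.a",
  "near.a"            = "nearness.a",
  "necessary.a"       = "need_attr.a",
  "essential.a"       = "need_attr.a",
  "quiet.a"           = "calmness.a",
  "calm.a"            = "calmness.a",
  "restless.a"        = "calmness.a",
  "mental.a"          = "mind_attr.a",
  "cognitive.a"       = "mind_attr.a",
  "inappropriate.a"   = "propriety.a",
  "improper.a"        = "propriety.a",
  "unable.a"          = "ability.a",
  "incapable.a"       = "ability.a",
  "reluctant.a"       = "willingness.a",
  "unwilling.a"       = "willingness.a",
  "extraneous.a"      = "relevance.a",
  "hard.a"            = "difficulty_attr.a",
  "difficult.a"       = "difficulty_attr.a",
  "easy.a"            = "difficulty_attr.a",
  # adverb clusters
  "often.r"           = "frequency.r",
  "frequently.r"      = "frequency.r",
  "constantly.r"      = "frequency.r",
  "usually.r"         = "frequency.r",
  "easily.r"          = "manner.r",
  "readily.r"         = "manner.r",
  "quietly.r"         = "manner.r",
  "quickly.r"         = "manner.r",
  "directly.r"        = "manner.r",
  "excessively.r"     = "degree.r",
  "very.r"            = "degree.r"
)

# word -> sense nodes. Synonym groups share one node.
TAXO_SENSES <- list(
  seat = "seat.n", chair = c("chair.n", "seat.n"), table = "table.n",
  motor = "motor.n", toy = "toy.n", tool = "tool.n", book = "book.n",
  clothes = "clothes.n", thing = "thing.n", object = "object.n",
  item = "thing.n", belonging = "thing.n", material = "thing.n",
  hand = "hand.n", foot = "foot.n", face = "face.n", tooth = "tooth.n",
  hair = "hair.n", child = "child.n", parent = "parent.n",
  teacher = "teacher.n", friend = "friend.n", sibling = "child.n",
  adult = "person.n", person = "person.n", food = "food.n",
  room = "room.n", classroom = "classroom.n", school = "school.n",
  home = "home.n", house = "house.n", attention = "attention.n",
  memory = "memory.n", interest = "interest.n", sadness = "sadness.n",
  anger = "anger.n", temper = "anger.n", fear = "fear.n",
  mood = "mood.n", effort = "effort.n", energy = "energy.n",
  difficulty = "difficulty.n", trouble = "difficulty.n",
  situation = "situation.n", behavior = "behavior.n",
  symptom = "symptom.n", appetite = "appetite.n", question = "question.n",
  answer = c("answer.n", "answer.v"), instruction = "instruction.n",
  rule = "rule.n", conversation = "conversation.n", story = "story.n",
  detail = "detail.n", picture = "picture.n", activity = "activity.n",
  task = "task.n", chore = "task.n", assignment = "task.n",
  work = "work.n", homework = "homework.n", game = "game.n",
  leisure = "leisure.n", mistake = "mistake.n", error = "mistake.n",
  turn = "turn.n", tantrum = "tantrum.n", act = c("act.n", "act.v"),
  day = "day.n", night = "night.n", morning = "morning.n",
  bedtime = "bedtime.n", meal = "meal.n",
  run = "run.v", climb = "climb.v", walk = "walk.v", jump = "jump.v",
  leave = "leave.v", go = "go.v", come = "come.v", drive = "drive.v",
  fidget = "fidget.v", squirm = "squirm.v", wiggle = "wiggle.v",
  tap = "tap.v", sit = "sit.v", stand = "stand.v", throw = "throw.v",
  talk = "talk.v", say = "say.v", tell = "tell.v", ask = "ask.v",
  blurt = "blurt.v", interrupt = "interrupt.v", intrude = "interrupt.v",
  shout = "shout.v", scream = "scream.v", argue = "argue.v",
  listen = "listen.v", hear = "hear.v", see = "see.v", watch = "watch.v",
  notice = "notice.v", organize = "organize.v", organise = "organize.v",
  plan = "plan.v", arrange = "organize.v", concentrate = "concentrate.v",
  attend = "attend.v", focus = "focus.v", remember = "remember.v",
  forget = "forget.v", lose = "lose.v", misplace = "lose.v",
  give = "give.v", take = "take.v", get = "get.v", steal = "steal.v",
  share = "share.v", make = "make.v", create = "create.v",
  build = "build.v", draw = "draw.v", write = "write.v",
  sustain = "sustain.v", maintain = "maintain.v", keep = "keep.v",
  remain = "remain.v", stay = "stay.v", continue = "continue.v",
  wait = "wait.v", fail = "fail.v", neglect = "neglect.v",
  avoid = "avoid.v", refuse = "refuse.v", ignore = "ignore.v",
  finish = "finish.v", complete = "finish.v", end = "end.v",
  stop = "stop.v", start = "start.v", engage = "engage.v",
  participate = "participate.v", require = "require.v", need = "require.v",
  want = "want.v", expect = "expect.v", anticipate = "anticipate.v",
  distract = "distract.v", disturb = "disturb.v", bother = "bother.v",
  annoy = "annoy.v", seem = "seem.v", appear = "appear.v",
  follow = "follow.v", obey = "obey.v", help = "help.v", try = "try.v",
  feel = "feel.v", wake = "wake.v", eat = "eat.v", fight = "fight.v",
  hit = "hit.v", cry = "cry.v", whine = "whine.v", sulk = "sulk.v",
  defy = "defy.v", destroy = "destroy.v", blame = "blame.v",
  read = "read.v", wash = "wash.v", brush = "brush.v", dress = "dress.v",
  tidy = "tidy.v", have = "have.v", do = "do.v",
  play = c("play.n", "play.v"), sleep = c("sleep.n", "sleep.v"),
  worry = c("worry.n", "worry.v"),
  careless = "careless.a", careful = "careful.a", forgetful = "forgetful.a",
  close = "close.a", near = "near.a", necessary = "necessary.a",
  essential = "necessary.a", quiet = "quiet.a", calm = "calm.a",
  restless = "restless.a", mental = "mental.a", cognitive = "cognitive.a",
  inappropriate = "inappropriate.a", improper = "inappropriate.a",
  unable = "unable.a", incapable = "unable.a", reluctant = "reluctant.a",
  unwilling = "reluctant.a", extraneous = "extraneous.a", hard = "hard.a",
  difficult = "difficult.a", easy = "easy.a",
  often = "often.r", frequently = "often.r", constantly = "constantly.r",
  usually = "usually.r", easily = "easily.r", readily = "easily.r",
  quietly = "quietly.r", quickly = "quickly.r", directly = "directly.r",
  excessively = "excessively.r", very = "very.r"
)

# depth of every node (roots at depth 0), computed once at load
taxo_depths <- local({
  nodes <- unique(c(names(TAXO_PARENT), TAXO_PARENT))
  d <- integer(length(nodes)); names(d) <- nodes
  for (n in nodes) {
    depth <- 0L; cur <- n
    while (cur %in% names(TAXO_PARENT)) {
      cur <- TAXO_PARENT[[cur]]; depth <- depth + 1L
      if (depth > 50L) stop("cycle in taxonomy at ", n)
    }
    d[n] <- depth
  }
  d
})

taxo_ancestors <- function(node) {
  path <- node
  while (node %in% names(TAXO_PARENT)) {
    node <- TAXO_PARENT[[node]]
    path <- c(path, node)
  }
  path
}

#' Taxonomy version string
#'
#' Identifies the built-in hypernym taxonomy (recorded in outputs so that
#' lexical scores can be tied to the resource that produced them).
#' @return a single string.
#' @export
taxonomy_version <- function() {
  sprintf("symsim-taxonomy/1.0 (%d senses, %d nodes)",
          length(TAXO_SENSES), length(taxo_depths))
}

# Path similarity between two sense nodes: 1/(1 + path length) through the
# hypernym forest; NA if the senses live in different trees.
sense_path_similarity <- function(a, b) {
  if (a == b) return(1)
  anc_a <- taxo_ancestors(a); anc_b <- taxo_ancestors(b)
  common <- intersect(anc_a, anc_b)
  if (length(common) == 0L) return(NA_real_)
  # first common ancestor encountered is the deepest one
  lca <- common[which.max(taxo_depths[common])]
  len <- (taxo_depths[[a]] - taxo_depths[[lca]]) +
         (taxo_depths[[b]] - taxo_depths[[lca]])
  1 / (1 + len)
}

#' Taxonomy path similarity between two words
#'
#' Maximum of \code{1/(1 + path length)} over all sense pairs of the two
#' words in the built-in hypernym forest; \code{NA} when either word is out
#' of vocabulary or no sense pair is connected. An optional coarse POS
#' restricts each word's senses to that category.
#'
#' @param a,b lowercase lemmas.
#' @param pos_a,pos_b optional coarse POS (\code{"noun"}, \code{"verb"},
#'   \code{"adjective"}, \code{"adverb"}) restricting the senses considered.
#' @return similarity in (0, 1] or \code{NA}.
#' @export
path_similarity <- function(a, b, pos_a = NULL, pos_b = NULL) {
  sa <- TAXO_SENSES[[a]]; sb <- TAXO_SENSES[[b]]
  suffix <- c(noun = ".n", verb = ".v", adjective = ".a", adverb = ".r")
  if (!is.null(pos_a) && !is.null(sa)) {
    keep <- endsWith(sa, suffix[[pos_a]])
    if (any(keep)) sa <- sa[keep]
  }
  if (!is.null(pos_b) && !is.null(sb)) {
    keep <- endsWith(sb, suffix[[pos_b]])
    if (any(keep)) sb <- sb[keep]
  }
  if (is.null(sa) || is.null(sb)) return(NA_real_)
  best <- NA_real_
  for (x in sa) for (y in sb) {
    s <- sense_path_similarity(x, y)
    if (!is.na(s) && (is.na(best) || s > best)) best <- s
  }
  best
}
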